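# The csagen XML dialect

Connection-set expressions serialize to a purpose-built XML schema (root tag
`CSA`, attribute `version="1.0"`).  The structure is inspired by MathML's
apply/operand nesting but fully specified here.  Unknown elements are
rejected by the parser, never silently dropped.  Seeds are mandatory on
every random node so that a parsed document reproduces the identical
realization on any machine.

## Grammar

```
document       := <CSA version="1.0"> expr-or-cset </CSA>
expr-or-cset   := mask-expr | connection-set
connection-set := <connectionSet> mask-expr valueSet* </connectionSet>
mask-expr      := leaf | operator
operator       := <intersection> mask-expr mask-expr </intersection>
                | <union>        mask-expr mask-expr </union>
                | <difference>   mask-expr mask-expr </difference>
leaf           := <oneToOne/>
                | <full/>
                | <random p="P" seed="S"/>
                | <cross> <sources> interval* </sources>
                          <targets> interval* </targets> </cross>
                | <explicit> <connection i="I" j="J"/>* </explicit>
interval       := <interval lo="L" hi="H"/>          (closed bounds)
valueSet       := <valueSet kind="constant" value="V"/>
                | <valueSet kind="uniform" lo="L" hi="H" seed="S"/>
                | <valueSet kind="distanceDelay" velocity="V" base="B"
                            sigma="G" lo="L" hi="H" seed="S">
                    <positions role="source"> pos* </positions>
                    <positions role="target"> pos* </positions>
                  </valueSet>
pos            := <pos id="I" x="X" y="Y" [z="Z"]/>
```

Real-valued attributes are written with 17 significant digits so round-trips
are bit-exact.  Custom (function-backed) value sets and function-backed
positions are not serializable; `serialize_csa()` rejects them.

## Example

Random Erdős–Rényi connectivity without self-connections, with a constant
weight and a uniform random delay:

```xml
<CSA version="1.0">
  <connectionSet>
    <difference>
      <random p="0.10000000000000001" seed="42"/>
      <oneToOne/>
    </difference>
    <valueSet kind="constant" value="2"/>
    <valueSet kind="uniform" lo="0.5" hi="1.5" seed="7"/>
  </connectionSet>
</CSA>
```
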