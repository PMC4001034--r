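<?xml version="1.0" encoding="UTF-8"?>
<CSA version="1.0">
  <connectionSet>
    <difference>
      <random p="0.5" seed="42"/>
      <oneToOne/>
    </difference>
    <valueSet kind="constant" value="2"/>
    <valueSet kind="uniform" lo="0.5" hi="1.5" seed="7"/>
  </connectionSet>
</CSA>
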