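#' Serialize a connection-set expression to XML
#'
#' Connection-set expressions serialize to a small XML dialect so that a
#' description can be prepared on one machine (or by an external tool, or by
#' hand) and re-instantiated on another.  The document root is `<CSA
#' version="1.0">`; inside it an expression tree of operator elements
#' (`intersection`, `union`, `difference`, each with exactly two children)
#' over leaf elements (`oneToOne`, `random p= seed=`, `cross` with
#' `sources`/`targets` interval lists, `explicit` with `connection i= j=`
#' children, `full`).  An expression with value sets serializes as a
#' `connectionSet` element holding the mask expression followed by
#' `valueSet` elements.  Seeds are mandatory attributes of every random
#' node, so a parsed document reproduces the identical realization on any
#' machine.  Numeric attributes use 17 significant digits, so round-trips
#' are bit-exact.  See `inst/xml-dialect.md` for the full schema.
#'
#' @param x a mask expression, connection-set, or connection generator
#'   (its expression is serialized).
#' @return A single string of well-formed XML; deterministic for a given
#'   expression.
#' @examples
#' xml <- serialize_csa(csa_difference(random_mask(0.1, seed = 42), delta()))
#' g <- from_xml(xml)
#' @export
serialize_csa <- function(x) {
  if (inherits(x, "connection_generator")) x <- x$expr
  doc <- xml2::xml_new_root("CSA", version = "1.0")
  if (inherits(x, "csa_cset")) {
    node <- xml2::xml_add_child(doc, "connectionSet")
    xml_write_mask(node, x$mask)
    for (v in x$value_sets) xml_write_value_set(node, v)
  } else if (inherits(x, "csa_mask")) {
    xml_write_mask(doc, x)
  } else {
    stop("x must be a mask expression or a connection-set")
  }
  as.character(doc)
}

num_attr <- function(x) sprintf("%.17g", x)

xml_write_mask <- function(parent, m) {
  switch(m$kind,
    one_to_one = xml2::xml_add_child(parent, "oneToOne"),
    full = xml2::xml_add_child(parent, "full"),
    random = xml2::xml_add_child(parent, "random",
                                 p = num_attr(m$p), seed = as.character(m$seed)),
    cross = {
      node <- xml2::xml_add_child(parent, "cross")
      xml_write_intervals(xml2::xml_add_child(node, "sources"), m$sources)
      xml_write_intervals(xml2::xml_add_child(node, "targets"), m$targets)
    },
    explicit = {
      node <- xml2::xml_add_child(parent, "explicit")
      for (r in seq_len(nrow(m$pairs)))
        xml2::xml_add_child(node, "connection",
                            i = as.character(m$pairs[r, "i"]),
                            j = as.character(m$pairs[r, "j"]))
    },
    operator = {
      node <- xml2::xml_add_child(parent, m$op)
      xml_write_mask(node, m$left)
      xml_write_mask(node, m$right)
    },
    stop("cannot serialize mask kind: ", m$kind))
  invisible(parent)
}

xml_write_intervals <- function(parent, s) {
  for (k in seq_along(s$lo))
    xml2::xml_add_child(parent, "interval",
                        lo = as.character(s$lo[k]), hi = as.character(s$hi[k]))
  invisible(parent)
}

xml_write_value_set <- function(parent, v) {
  if (!isTRUE(v$serializable))
    stop("value set of kind '", v$kind,
         "' is not serializable (function-backed evaluator)")
  p <- v$params
  switch(v$kind,
    constant = xml2::xml_add_child(parent, "valueSet", kind = "constant",
                                   value = num_attr(p$value)),
    uniform = xml2::xml_add_child(parent, "valueSet", kind = "uniform",
                                  lo = num_attr(p$lo), hi = num_attr(p$hi),
                                  seed = as.character(p$seed)),
    distance_delay = {
      node <- xml2::xml_add_child(parent, "valueSet", kind = "distanceDelay",
                                  velocity = num_attr(p$velocity),
                                  base = num_attr(p$base),
                                  sigma = num_attr(p$sigma),
                                  lo = num_attr(p$lo), hi = num_attr(p$hi),
                                  seed = as.character(p$seed))
      xml_write_positions(node, "source", p$pos_source)
      xml_write_positions(node, "target", p$pos_target)
    },
    stop("value set of kind '", v$kind, "' is not serializable"))
  invisible(parent)
}

xml_write_positions <- function(parent, role, tab) {
  node <- xml2::xml_add_child(parent, "positions", role = role)
  for (r in seq_len(nrow(tab))) {
    attrs <- c(list(node, "pos", id = as.character(tab$id[r]),
                    x = num_attr(tab$x[r]), y = num_attr(tab$y[r])),
               if ("z" %in% names(tab)) list(z = num_attr(tab$z[r])))
    do.call(xml2::xml_add_child, attrs)
  }
  invisible(parent)
}

# ---- parsing: the builtin parser for the "CSA" dialect --------------------

req_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v))
    stop("element <", xml2::xml_name(node), "> lacks required attribute '",
         name, "'")
  v
}

parse_csa_document <- function(doc) {
  root <- xml2::xml_root(doc)
  kids <- xml2::xml_children(root)
  if (length(kids) != 1L)
    stop("<CSA> must contain exactly one expression element")
  parse_csa_node(kids[[1L]])
}

parse_csa_node <- function(node) {
  name <- xml2::xml_name(node)
  kids <- xml2::xml_children(node)
  switch(name,
    oneToOne = delta(),
    full = full_mask(),
    random = random_mask(p = as.double(req_attr(node, "p")),
                         seed = as.integer(req_attr(node, "seed"))),
    cross = {
      if (length(kids) != 2L ||
          !identical(xml2::xml_name(kids[[1L]]), "sources") ||
          !identical(xml2::xml_name(kids[[2L]]), "targets"))
        stop("<cross> must contain <sources> then <targets>")
      cross_mask(parse_intervals(kids[[1L]]), parse_intervals(kids[[2L]]))
    },
    explicit = {
      pairs <- t(vapply(kids, function(k) {
        if (!identical(xml2::xml_name(k), "connection"))
          stop("unknown element <", xml2::xml_name(k), "> inside <explicit>")
        c(as.integer(req_attr(k, "i")), as.integer(req_attr(k, "j")))
      }, integer(2)))
      if (length(kids) == 0L) pairs <- matrix(integer(), ncol = 2L)
      explicit_mask(pairs)
    },
    intersection = ,
    union = ,
    difference = {
      if (length(kids) != 2L)
        stop("<", name, "> must have exactly two children")
      combine(name, parse_csa_node(kids[[1L]]), parse_csa_node(kids[[2L]]))
    },
    connectionSet = {
      if (length(kids) < 1L) stop("<connectionSet> must contain a mask expression")
      mask <- parse_csa_node(kids[[1L]])
      values <- lapply(kids[-1L], parse_value_set)
      do.call(cset, c(list(mask), values))
    },
    stop("unknown element <", name, "> in CSA document")
  )
}

parse_intervals <- function(node) {
  kids <- xml2::xml_children(node)
  lo <- integer(length(kids)); hi <- integer(length(kids))
  for (k in seq_along(kids)) {
    if (!identical(xml2::xml_name(kids[[k]]), "interval"))
      stop("unknown element <", xml2::xml_name(kids[[k]]), "> in interval list")
    lo[k] <- as.integer(req_attr(kids[[k]], "lo"))
    hi[k] <- as.integer(req_attr(kids[[k]], "hi"))
  }
  interval_set(lo, hi)
}

parse_value_set <- function(node) {
  if (!identical(xml2::xml_name(node), "valueSet"))
    stop("unknown element <", xml2::xml_name(node), "> in <connectionSet>")
  kind <- req_attr(node, "kind")
  switch(kind,
    constant = vs_constant(as.double(req_attr(node, "value"))),
    uniform = vs_uniform(lo = as.double(req_attr(node, "lo")),
                         hi = as.double(req_attr(node, "hi")),
                         seed = as.integer(req_attr(node, "seed"))),
    distanceDelay = {
      kids <- xml2::xml_children(node)
      roles <- vapply(kids, function(k) xml2::xml_attr(k, "role"), "")
      if (!all(vapply(kids, xml2::xml_name, "") == "positions") ||
          !setequal(roles, c("source", "target")))
        stop("<valueSet kind='distanceDelay'> needs <positions role='source'> ",
             "and <positions role='target'>")
      vs_distance_delay(
        pos_source = parse_positions(kids[[which(roles == "source")]]),
        pos_target = parse_positions(kids[[which(roles == "target")]]),
        velocity = as.double(req_attr(node, "velocity")),
        base = as.double(req_attr(node, "base")),
        sigma = as.double(req_attr(node, "sigma")),
        lo = as.double(req_attr(node, "lo")),
        hi = as.double(req_attr(node, "hi")),
        seed = as.integer(req_attr(node, "seed")))
    },
    stop("unknown valueSet kind: ", kind))
}

parse_positions <- function(node) {
  kids <- xml2::xml_children(node)
  tab <- data.frame(
    id = vapply(kids, function(k) as.integer(req_attr(k, "id")), integer(1)),
    x = vapply(kids, function(k) as.double(req_attr(k, "x")), numeric(1)),
    y = vapply(kids, function(k) as.double(req_attr(k, "y")), numeric(1)))
  z <- vapply(kids, function(k) xml2::xml_attr(k, "z"), "")
  if (all(!is.na(z))) tab$z <- as.double(z)
  tab
}

#' Instantiate a connection generator from XML
#'
#' Parses the XML representation of a connection generator and returns it.
#' The document's root tag selects the parser: the registry maps tags
#' (identifying connectivity-description languages) to parser plugins — see
#' [select_cg_implementation()].  The built-in dialect uses root tag `CSA`.
#' The returned generator has no masks set yet; the consumer supplies its
#' windows via [cg_set_mask()]/[cg_set_masks()].
#'
#' @param xml a string of XML.
#' @param path path of an XML file (`from_xml_file` is `from_xml` on the
#'   file's contents).
#' @return A [connection_generator()].
#' @export
from_xml <- function(xml) {
  doc <- xml2::read_xml(xml)
  tag <- xml2::xml_name(xml2::xml_root(doc))
  parser <- registry_parser(tag)
  expr <- parser(doc)
  connection_generator(expr)
}

#' @rdname from_xml
#' @export
from_xml_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  from_xml(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
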