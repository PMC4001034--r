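# The parser registry maps XML root tags (identifying connectivity
# description languages) to parser functions, and the plugin registry maps
# library names to in-process plugins that provide such parsers.  Dynamic
# shared-object loading of connection libraries is reinterpreted here as
# plugin discovery in the host R session.

.registry <- new.env(parent = emptyenv())
.registry$parsers <- list()   # tag -> list(parser, library)
.registry$plugins <- list()   # library name -> list(parsers = list(tag = fn))

#' Register a connection-generator library (plugin)
#'
#' A plugin is an in-process stand-in for a dynamically loadable
#' connectivity library: a named entry exposing `parsers`, a named list
#' mapping XML root tags to parser functions `function(doc) -> expression`.
#' Registering a library makes it selectable with
#' [select_cg_implementation()]; it does not by itself bind any tag.
#'
#' @param name the library's name.
#' @param parsers named list of parser functions, keyed by XML root tag.
#' @return Invisibly, the library name.
#' @export
register_cg_library <- function(name, parsers) {
  if (!is.character(name) || length(name) != 1L) stop("name must be a string")
  if (!is.list(parsers) || is.null(names(parsers)) ||
      !all(nzchar(names(parsers))) ||
      !all(vapply(parsers, is.function, logical(1))))
    stop("parsers must be a named list of functions, keyed by XML tag")
  .registry$plugins[[name]] <- list(parsers = parsers)
  invisible(name)
}

#' Bind an XML tag to a parser library
#'
#' Associates the document root tag `tag` with the library `library`:
#' subsequent [from_xml()] calls on documents with that root tag dispatch to
#' the parser that the library registered for it.  Re-selecting a tag
#' replaces the previous binding with a warning (last registration wins).
#'
#' @param tag an XML root tag, e.g. `"CSA"`.
#' @param library name of a library previously registered with
#'   [register_cg_library()].
#' @return Invisibly, the tag.
#' @examples
#' select_cg_implementation("CSA", "csagen")   # the built-in dialect
#' @export
select_cg_implementation <- function(tag, library) {
  plugin <- .registry$plugins[[library]]
  if (is.null(plugin))
    stop("no such connection-generator library: '", library, "' (registered: ",
         paste(names(.registry$plugins), collapse = ", "), ")")
  parser <- plugin$parsers[[tag]]
  if (is.null(parser))
    stop("library '", library, "' provides no parser for tag <", tag, ">")
  prev <- .registry$parsers[[tag]]
  if (!is.null(prev) && !identical(prev$library, library))
    warning("replacing parser for tag <", tag, ">: '", prev$library,
            "' -> '", library, "'")
  .registry$parsers[[tag]] <- list(parser = parser, library = library)
  invisible(tag)
}

#' @rdname select_cg_implementation
#' @export
registered_cg_tags <- function() names(.registry$parsers)

registry_parser <- function(tag) {
  entry <- .registry$parsers[[tag]]
  if (is.null(entry)) {
    known <- registered_cg_tags()
    stop("no parser registered for root tag <", tag, ">; registered tags: ",
         if (length(known)) paste(known, collapse = ", ") else "(none)")
  }
  entry$parser
}

.onLoad <- function(libname, pkgname) {
  register_cg_library("csagen", parsers = list(CSA = parse_csa_document))
  select_cg_implementation("CSA", "csagen")
}
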