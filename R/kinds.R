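#' @title Data kinds
#' @description
#' The work graph is nominally typed: every operation port carries a
#' `wg_kind`, and two kinds are compatible iff their tags match recursively.
#' There is no implicit coercion (no integer -> real promotion), so wiring
#' mistakes fail at graph-build time rather than at execution time.
#'
#' Scalar tags are `boolean`, `integer`, `real`, `text`, `file_path`, plus
#' two extensions used internally: `data` (opaque structured payloads such
#' as simulation inputs) and `any` (unknown; unifies with everything, used
#' for wrapped operations whose input kinds are inferred from bound values
#' and for the empty array). Arrays are `array_of(<kind>)` with nesting
#' depth at most 2.
#' @name kinds
NULL

wg_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "wg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Construct a data kind
#'
#' @param tag one of `"boolean"`, `"integer"`, `"real"`, `"text"`,
#'   `"file_path"`, `"data"`, `"any"`, `"array"`.
#' @param elem element kind, required when `tag == "array"`.
#' @return a `wg_kind` object.
#' @export
wg_kind <- function(tag, elem = NULL) {
  valid <- c("boolean", "integer", "real", "text", "file_path", "data", "any", "array")
  if (!tag %in% valid) {
    wg_error("wg_unknown_kind", sprintf("unknown kind tag '%s'", tag))
  }
  if (tag == "array") {
    if (is.null(elem)) wg_error("wg_unknown_kind", "array kind requires an element kind")
    if (array_depth(elem) >= 2) {
      wg_error("wg_unknown_kind", "array nesting depth exceeds 2")
    }
  }
  structure(list(tag = tag, elem = elem), class = "wg_kind")
}

array_depth <- function(kind) {
  if (kind$tag != "array") 0L else 1L + array_depth(kind$elem)
}

#' @rdname kinds
#' @export
k_boolean <- function() wg_kind("boolean")
#' @rdname kinds
#' @export
k_integer <- function() wg_kind("integer")
#' @rdname kinds
#' @export
k_real <- function() wg_kind("real")
#' @rdname kinds
#' @export
k_text <- function() wg_kind("text")
#' @rdname kinds
#' @export
k_file <- function() wg_kind("file_path")
#' @rdname kinds
#' @export
k_data <- function() wg_kind("data")
#' @rdname kinds
#' @export
k_any <- function() wg_kind("any")
#' @rdname kinds
#' @param elem element kind
#' @export
k_array <- function(elem = k_any()) wg_kind("array", elem)

#' @export
format.wg_kind <- function(x, ...) {
  if (x$tag == "array") paste0("array_of(", format(x$elem), ")") else x$tag
}

#' @export
print.wg_kind <- function(x, ...) {
  cat("<kind ", format(x), ">\n", sep = "")
  invisible(x)
}

#' Are two kinds compatible?
#'
#' Tags must match recursively; the `any` tag unifies with everything
#' (it marks inferred/unknown kinds, e.g. the element kind of an empty
#' array or the ports of wrapped user procedures).
#'
#' @param a,b `wg_kind` objects.
#' @return logical scalar.
#' @export
kind_compatible <- function(a, b) {
  if (a$tag == "any" || b$tag == "any") return(TRUE)
  if (a$tag != b$tag) return(FALSE)
  if (a$tag == "array") return(kind_compatible(a$elem, b$elem))
  TRUE
}

scalar_tag_of <- function(value) {
  if (is.logical(value)) "boolean"
  else if (is.integer(value)) "integer"
  else if (is.double(value)) "real"
  else if (is.character(value)) "text"
  else NA_character_
}

#' Infer the kind of an R value
#'
#' Length-1 atomic vectors map to the matching scalar kind; longer atomic
#' vectors and homogeneous bare lists map to `array_of(<elem>)`; classed
#' structured objects (simulation inputs, systems, ...) map to `data`.
#' Heterogeneous lists are rejected.
#'
#' @param value any supported payload.
#' @return a `wg_kind`.
#' @export
infer_kind <- function(value) {
  if (inherits(value, "wg_kind")) return(value)
  if (is.atomic(value) && !is.null(value) && is.null(attr(value, "class"))) {
    tag <- scalar_tag_of(value)
    if (is.na(tag)) wg_error("wg_unsupported_payload", "unsupported atomic payload")
    if (length(value) == 1L) return(wg_kind(tag))
    return(k_array(wg_kind(tag)))
  }
  if (is.list(value) && is.null(attr(value, "class"))) {
    if (length(value) == 0L) return(k_array(k_any()))
    elems <- lapply(value, infer_kind)
    first <- elems[[1L]]
    for (e in elems[-1L]) {
      if (!identical(format(e), format(first))) {
        wg_error("wg_unsupported_payload", "heterogeneous array payload")
      }
    }
    if (array_depth(first) >= 2) {
      wg_error("wg_unsupported_payload", "array nesting depth exceeds 2")
    }
    return(k_array(first))
  }
  if (is.object(value)) return(k_data())
  wg_error("wg_unsupported_payload", "unsupported payload type")
}

#' Does a value conform to a kind?
#'
#' Conformance is checked on payloads at binding and at output-caching
#' time. `file_path` accepts length-1 character values; `data` accepts any
#' structured object; `any` accepts everything.
#'
#' @param value payload.
#' @param kind `wg_kind`.
#' @return logical scalar.
#' @export
value_conforms <- function(value, kind) {
  switch(kind$tag,
    any = TRUE,
    data = TRUE,
    boolean = is.logical(value) && length(value) == 1L,
    integer = is.integer(value) && length(value) == 1L,
    real = is.double(value) && length(value) == 1L,
    text = is.character(value) && length(value) == 1L,
    file_path = is.character(value) && length(value) == 1L,
    array = {
      if (is.atomic(value) && is.null(attr(value, "class"))) {
        kind$elem$tag %in% c("any", scalar_tag_of(value)) || length(value) == 0L
      } else if (is.list(value) && is.null(attr(value, "class"))) {
        all(vapply(value, value_conforms, logical(1), kind = kind$elem))
      } else FALSE
    },
    FALSE
  )
}

# Coerce a JSON-decoded payload back onto its declared kind (jsonlite reads
# every number as double and scalars as length-1 vectors).
coerce_to_kind <- function(value, kind) {
  switch(kind$tag,
    integer = as.integer(value),
    real = as.double(value),
    boolean = as.logical(value),
    text = as.character(value),
    file_path = as.character(value),
    array = {
      if (kind$elem$tag %in% c("integer", "real", "boolean", "text", "file_path")) {
        # scalar element kinds live in atomic vectors
        coerce_elem_vec(unlist(value), kind$elem)
      } else if (is.list(value)) {
        lapply(value, coerce_to_kind, kind = kind$elem)
      } else value
    },
    value
  )
}

coerce_elem_vec <- function(value, elem) {
  switch(elem$tag,
    integer = as.integer(value),
    real = as.double(value),
    boolean = as.logical(value),
    text = as.character(value),
    file_path = as.character(value),
    value
  )
}

kind_to_list <- function(kind) {
  if (is.null(kind)) return(NULL)
  if (kind$tag == "array") list(tag = "array", elem = kind_to_list(kind$elem))
  else list(tag = kind$tag)
}

kind_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (identical(x$tag, "array")) wg_kind("array", kind_from_list(x$elem)) else wg_kind(x$tag)
}
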