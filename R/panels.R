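#' Marker panels and name standardization
#'
#' A marker panel is the ordered set of protein markers imaged in one
#' experiment. Panels differ across datasets; cross-dataset training relies
#' on mapping every raw marker (and cell-type) name to a canonical form.
#'
#' @param canonical_names character vector of unique canonical marker names.
#' @param alias_map named character vector mapping raw name -> canonical name
#'   (may be empty). Canonical names always map to themselves.
#' @return An object of class `marker_panel`.
#' @examples
#' p <- marker_panel(c("CD45", "Pan-Keratin"), c(PanCK = "Pan-Keratin"))
#' standardize_names(c("PanCK", "CD45"), p$alias_map)
#' @export
marker_panel <- function(canonical_names, alias_map = character()) {
  stopifnot(is.character(canonical_names), length(canonical_names) >= 1L)
  if (anyDuplicated(canonical_names))
    stop("canonical marker names must be unique", call. = FALSE)
  if (length(alias_map)) {
    if (is.null(names(alias_map)) || any(!nzchar(names(alias_map))))
      stop("alias_map must be a named character vector", call. = FALSE)
    if (anyDuplicated(names(alias_map)))
      stop("each alias must map to exactly one canonical name", call. = FALSE)
  }
  structure(list(canonical_names = canonical_names,
                 alias_map = alias_map),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$canonical_names), " markers, ",
      length(x$alias_map), " aliases\n", sep = "")
  invisible(x)
}

#' Map raw marker or cell-type names to canonical names
#'
#' Canonical input is passed through unchanged (idempotent). In strict mode
#' an unmapped name is an error; in lenient mode it is passed through with a
#' warning.
#'
#' @param raw_names character vector of names as found in a dataset.
#' @param alias_map named character vector (raw -> canonical), or a
#'   `marker_panel`.
#' @param strict error on unmapped names (default `TRUE`)? Names already in
#'   canonical form (appearing as values of the map) never count as unmapped.
#' @return character vector of canonical names.
#' @export
standardize_names <- function(raw_names, alias_map, strict = TRUE) {
  if (inherits(alias_map, "marker_panel")) {
    canon <- alias_map$canonical_names
    alias_map <- alias_map$alias_map
  } else {
    canon <- unique(unname(alias_map))
  }
  out <- raw_names
  hit <- raw_names %in% names(alias_map)
  out[hit] <- unname(alias_map[raw_names[hit]])
  unknown <- !hit & !(raw_names %in% canon)
  if (any(unknown)) {
    terms <- paste(unique(raw_names[unknown]), collapse = ", ")
    if (strict)
      stop("unmapped name(s): ", terms, call. = FALSE)
    warning("passing through unmapped name(s): ", terms, call. = FALSE)
  }
  out
}

#' Read an alias map from CSV or JSON
#'
#' CSV files need columns `raw_name` and `canonical_name`; JSON files hold a
#' single object of raw -> canonical pairs.
#'
#' @param path file path.
#' @return named character vector (raw -> canonical).
#' @export
read_alias_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(unlist(m))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raw_name", "canonical_name") %in% names(df)))
    stop("alias CSV needs columns raw_name, canonical_name", call. = FALSE)
  structure(df$canonical_name, names = df$raw_name)
}
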