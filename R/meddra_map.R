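#' Construct a PT to SOC map
#'
#' Holds the primary-SOC mapping of MedDRA preferred terms to system organ
#' classes: each PT maps to exactly one SOC. Matching is case-insensitive on
#' trimmed text. MedDRA itself is licensed, so the table is user-supplied
#' (or generated by the synthetic-data module).
#'
#' @param pt Character vector of preferred terms.
#' @param soc Character vector of system organ classes, same length.
#' @return An object of class `pt_soc_map`.
#' @export
pt_soc_map <- function(pt, soc) {
  stopifnot(length(pt) == length(soc))
  pt <- trimws(as.character(pt))
  soc <- trimws(as.character(soc))
  key <- toupper(pt)
  tab <- tibble::tibble(pt = pt, soc = soc, key = key)
  tab <- dplyr::distinct(tab, .data$key, .data$soc, .keep_all = TRUE)
  dup <- tab$key[duplicated(tab$key)]
  if (length(dup)) {
    stop("PT mapped to more than one SOC: ",
         paste(unique(tab$pt[tab$key %in% dup]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(entries = tab[, c("pt", "soc", "key")],
                 soc_universe = sort(unique(soc)),
                 n_unmapped_queries = 0L),
            class = "pt_soc_map")
}

#' Load a PT to SOC map from a delimited file
#'
#' Expects a two-column file with header and columns `pt` and `soc`
#' (comma- or tab-delimited, sniffed from the header line). Duplicate
#' identical rows are collapsed; a PT mapped to two different SOCs is a data
#' error.
#'
#' @param path File path.
#' @return A `pt_soc_map` object.
#' @export
load_pt_soc_map <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  names(df) <- tolower(trimws(names(df)))
  if (!all(c("pt", "soc") %in% names(df))) {
    stop("PT-SOC map must have columns `pt` and `soc`: ", path,
         call. = FALSE)
  }
  pt_soc_map(df$pt, df$soc)
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat("<pt_soc_map> ", nrow(x$entries), " PTs across ",
      length(x$soc_universe), " SOCs\n", sep = "")
  invisible(x)
}

#' Map preferred terms to system organ classes
#'
#' Case-insensitive lookup on trimmed text. Unmapped PTs return the sentinel
#' SOC `"UNMAPPED"`; the number of unmapped queries is attached as the
#' `n_unmapped` attribute (a counted warning, not an error) so totals still
#' partition across SOCs.
#'
#' @param map A `pt_soc_map`.
#' @param pt Character vector of preferred terms.
#' @return Character vector of SOC names.
#' @export
#' @examples
#' m <- pt_soc_map("Muscle spasms",
#'                 "Musculoskeletal and connective tissue disorders")
#' map_pt(m, c("muscle SPASMS", "Nausea"))
map_pt <- function(map, pt) {
  stopifnot(inherits(map, "pt_soc_map"))
  key <- toupper(trimws(as.character(pt)))
  idx <- match(key, map$entries$key)
  out <- map$entries$soc[idx]
  out[is.na(idx)] <- "UNMAPPED"
  attr(out, "n_unmapped") <- sum(is.na(idx))
  out
}
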