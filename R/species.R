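#' Parse a fatty-acid species token
#'
#' Species are named with the shorthand used in gas-chromatography tables:
#' `"C:D"` for saturates (e.g. `"18:0"`), `"C:Dn-S"` for unsaturates with
#' the double-bond series counted from the methyl end (e.g. `"20:4n-6"`),
#' and a trailing `" DMA"` for dimethylacetals, the transmethylation
#' derivatives of plasmalogen vinyl-ether chains (e.g. `"16:0 DMA"`,
#' `"18:1n-9 DMA"`).
#'
#' @param name character vector of species tokens.
#' @return A data.frame with one row per token and columns `name`,
#'   `carbons`, `double_bonds`, `series` (one of `"saturate"`, `"n-9"`,
#'   `"n-7"`, `"n-6"`, `"n-3"`, `"DMA"`) and `is_dma`.
#' @examples
#' parse_species(c("18:0", "20:4n-6", "18:1n-9 DMA"))
#' @export
parse_species <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  out <- lapply(name, parse_species_one)
  do.call(rbind, out)
}

parse_species_one <- function(token) {
  raw <- token
  is_dma <- grepl(" DMA$", token)
  core <- sub(" DMA$", "", token)
  m <- regmatches(core, regexec("^([0-9]+):([0-9]+)(n-([9763]))?$", core))[[1]]
  if (length(m) == 0L) {
    stop("unparseable fatty-acid token: '", raw, "'", call. = FALSE)
  }
  carbons <- as.integer(m[2])
  db <- as.integer(m[3])
  series_suffix <- m[5]
  if (db == 0L && nzchar(series_suffix)) {
    stop("unparseable fatty-acid token: '", raw,
         "' (saturate cannot carry an n-series)", call. = FALSE)
  }
  if (db > 0L && !nzchar(series_suffix)) {
    stop("unparseable fatty-acid token: '", raw,
         "' (unsaturate requires an n-series suffix)", call. = FALSE)
  }
  series <- if (is_dma) "DMA" else if (db == 0L) "saturate" else paste0("n-", series_suffix)
  data.frame(name = raw, carbons = carbons, double_bonds = db,
             series = series, is_dma = is_dma, stringsAsFactors = FALSE)
}

#' Format a parsed species back to its token
#'
#' Inverse of [parse_species()]: rebuilds the `"C:Dn-S"`/`" DMA"` token
#' from the structural fields.
#'
#' @param sp data.frame as returned by [parse_species()].
#' @return character vector of tokens.
#' @export
format_species <- function(sp) {
  suffix <- ifelse(sp$double_bonds > 0L,
                   paste0("n-", sub("^n-", "", attr_series_number(sp))),
                   "")
  core <- paste0(sp$carbons, ":", sp$double_bonds, suffix)
  ifelse(sp$is_dma, paste0(core, " DMA"), core)
}

attr_series_number <- function(sp) {
  # for DMAs the n-series is recoverable from the stored name, not `series`
  ifelse(sp$series %in% c("n-9", "n-7", "n-6", "n-3"),
         sp$series,
         sub("^.*n-([9763]).*$", "n-\\1", sp$name))
}

is_species_token <- function(name) {
  vapply(name, function(x) {
    !inherits(try(parse_species_one(x), silent = TRUE), "try-error")
  }, logical(1), USE.NAMES = FALSE)
}
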