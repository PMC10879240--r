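#' Fatty-acid totals
#'
#' Sums of member species for the standard composition groupings.
#' DMAs (plasmalogen-derived dimethylacetals) are excluded from the
#' saturate/unsaturate totals and reported as their own total; LCPUFA are
#' species with >= 20 carbons and >= 2 double bonds.
#'
#' @param fa named numeric vector of species percentages (mol% of total
#'   fatty acids + DMAs), names parseable by [parse_species()].
#' @return named list with `total_saturates`, `total_mufa`, `total_n9`,
#'   `total_n7`, `total_n6`, `total_n3`, `total_lcpufa`, `total_dma`,
#'   `total_unsaturates`, `total_n6_lcpufa`.
#' @export
compute_totals <- function(fa) {
  if (length(fa) == 0L) stop("empty fatty-acid profile", call. = FALSE)
  sp <- parse_species(names(fa))
  v <- as.numeric(fa)
  dma <- sp$is_dma
  n_series <- attr_series_number(sp)  # n-series even for DMAs
  list(
    total_saturates  = sum(v[!dma & sp$double_bonds == 0L]),
    total_mufa       = sum(v[!dma & sp$double_bonds == 1L]),
    total_n9         = sum(v[!dma & n_series == "n-9" & sp$double_bonds > 0L]),
    total_n7         = sum(v[!dma & n_series == "n-7" & sp$double_bonds > 0L]),
    total_n6         = sum(v[!dma & n_series == "n-6" & sp$double_bonds > 0L]),
    total_n3         = sum(v[!dma & n_series == "n-3" & sp$double_bonds > 0L]),
    total_lcpufa     = sum(v[!dma & sp$carbons >= 20L & sp$double_bonds >= 2L]),
    total_n6_lcpufa  = sum(v[!dma & n_series == "n-6" &
                               sp$carbons >= 20L & sp$double_bonds >= 2L]),
    total_unsaturates = sum(v[!dma & sp$double_bonds >= 1L]),
    total_dma        = sum(v[dma])
  )
}

#' Unsaturation index
#'
#' UIx = sum over species of percentage x number of double bonds, DMAs
#' excluded. A packing/order proxy: 100% of a monoene gives 100, 100%
#' DHA (22:6n-3) gives 600.
#'
#' @inheritParams compute_totals
#' @return dimensionless index.
#' @export
unsaturation_index <- function(fa) {
  if (length(fa) == 0L) stop("empty fatty-acid profile", call. = FALSE)
  sp <- parse_species(names(fa))
  sum(as.numeric(fa)[!sp$is_dma] * sp$double_bonds[!sp$is_dma])
}

# peroxidability weights by double-bond count (monoenes barely peroxidize;
# susceptibility grows steeply with bis-allylic positions)
PIX_WEIGHTS <- c(`1` = 0.025, `2` = 1, `3` = 2, `4` = 4, `5` = 6, `6` = 8)

#' Peroxidability index
#'
#' PIx = 0.025 x monoenes + 1 x dienes + 2 x trienes + 4 x tetraenes +
#' 6 x pentaenes + 8 x hexaenes (percent units), DMAs excluded.
#'
#' @inheritParams compute_totals
#' @return dimensionless index.
#' @export
peroxidability_index <- function(fa) {
  if (length(fa) == 0L) stop("empty fatty-acid profile", call. = FALSE)
  sp <- parse_species(names(fa))
  keep <- !sp$is_dma & sp$double_bonds >= 1L
  w <- PIX_WEIGHTS[as.character(sp$double_bonds[keep])]
  if (any(is.na(w))) {
    stop("no peroxidability weight for species with ",
         paste(unique(sp$double_bonds[keep][is.na(w)]), collapse = ", "),
         " double bonds", call. = FALSE)
  }
  sum(as.numeric(fa)[keep] * w)
}

#' Lipid-class ratios and sphingolipid total
#'
#' CHO/SE (an index of cholesterol esterification activity), the
#' anionic-to-zwitterionic phospholipid ratio (PG+PI+PS)/(PC+PE) (a
#' surface-charge proxy; SM is counted with the sphingolipids, not the
#' zwitterionic pool), and total sphingolipids SM+SULF+OTHER_SL.
#' Zero denominators yield `NaN` rather than an error.
#'
#' @param lc named numeric vector of lipid-class percentages.
#' @return named list `cho_se_ratio`, `anionic_zwitterionic_ratio`,
#'   `total_sphingolipids`.
#' @export
class_ratios <- function(lc) {
  g <- function(tok) if (tok %in% names(lc)) as.numeric(lc[[tok]]) else 0
  safe_div <- function(num, den) if (den > 0) num / den else NaN
  list(
    cho_se_ratio = safe_div(g("CHO"), g("SE")),
    anionic_zwitterionic_ratio =
      safe_div(g("PG") + g("PI") + g("PS"), g("PC") + g("PE")),
    total_sphingolipids = g("SM") + g("SULF") + g("OTHER_SL")
  )
}

#' Full derived-index set for one subject
#'
#' Combines [compute_totals()], [unsaturation_index()],
#' [peroxidability_index()] and [class_ratios()] into the complete set of
#' derived variables analysed downstream. The saturate-to-unsaturate
#' ratio excludes DMAs from both numerator and denominator (DMAs proxy
#' plasmalogen ether chains and are analysed separately).
#'
#' @inheritParams compute_totals
#' @inheritParams class_ratios
#' @return one-row data.frame of derived indexes.
#' @export
derived_index_set <- function(fa, lc) {
  tot <- compute_totals(fa)
  safe_div <- function(num, den) if (is.finite(den) && den > 0) num / den else NaN
  data.frame(
    tot[c("total_saturates", "total_mufa", "total_n9", "total_n7",
          "total_n6", "total_n3", "total_lcpufa", "total_n6_lcpufa",
          "total_dma")],
    sat_unsat_ratio = safe_div(tot$total_saturates, tot$total_unsaturates),
    n3_n6_ratio = safe_div(tot$total_n3, tot$total_n6),
    uix = unsaturation_index(fa),
    pix = peroxidability_index(fa),
    class_ratios(lc),
    stringsAsFactors = FALSE
  )
}

#' Derived indexes for every subject in a cohort
#'
#' @param cohort a `raft_cohort`.
#' @return data.frame with `subject_id`, `group` and one column per
#'   derived index, one row per subject.
#' @export
derive_indexes <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    fa <- unlist(cohort[i, fa_cols(cohort), drop = FALSE])
    lc <- unlist(cohort[i, class_cols(cohort), drop = FALSE])
    cbind(cohort[i, c("subject_id", "group"), drop = FALSE],
          derived_index_set(fa, lc), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Export per-subject derived indexes as JSON
#'
#' @param cohort a `raft_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_indexes_json <- function(cohort, path) {
  idx <- derive_indexes(cohort)
  jsonlite::write_json(idx, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
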