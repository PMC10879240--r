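#' @title Lipid profile containers
#' @description
#' A cohort is stored as a plain data.frame, one row per subject, with the
#' metadata columns `subject_id`, `group`, `sex`, `age`, `pmd` followed by
#' one column per fatty-acid token (mol% of total fatty acids + DMAs) and
#' one per lipid-class token (% of total lipid). Which columns belong to
#' which table is carried in the `"fa_cols"` / `"class_cols"` attributes
#' and recovered automatically by [as_raft_cohort()].
#' @name raft_cohort
NULL

#' Known lipid-class tokens
#'
#' PC/PE: zwitterionic glycerophospholipids; PS/PI/PG: anionic
#' glycerophospholipids; SM: sphingomyelin; SULF: sulfatides; OTHER_SL:
#' remaining sphingolipids; CHO: free cholesterol; SE: cholesteryl
#' (sterol) esters.
#' @export
LIPID_CLASSES <- c("PC", "PE", "PS", "PI", "PG", "SM", "SULF", "OTHER_SL",
                   "CHO", "SE")

COHORT_META <- c("subject_id", "group", "sex", "age", "pmd")

#' Construct/validate a raft cohort data.frame
#'
#' Identifies fatty-acid and lipid-class columns, checks the closure
#' invariant (each compositional table should sum to 100 per subject;
#' deviations beyond `warn_tol` warn, beyond `error_tol` stop) and tags
#' the result with class `"raft_cohort"`.
#'
#' @param df data.frame with metadata, species and class columns.
#' @param warn_tol,error_tol closure tolerances on the per-subject sum
#'   (percent units). Densitometry/GC tables rarely close exactly.
#' @return the validated `raft_cohort` data.frame.
#' @export
as_raft_cohort <- function(df, warn_tol = 1, error_tol = 5) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(c("subject_id", "group"), names(df))
  if (length(miss)) {
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  other <- setdiff(names(df), COHORT_META)
  class_cols <- intersect(other, LIPID_CLASSES)
  fa_candidates <- setdiff(other, class_cols)
  ok <- is_species_token(fa_candidates)
  if (any(!ok)) {
    # surface the grammar error for the first offending column
    parse_species_one(fa_candidates[!ok][1])
  }
  fa_cols <- fa_candidates
  for (blk in list(list(cols = fa_cols, what = "fatty-acid"),
                   list(cols = class_cols, what = "lipid-class"))) {
    if (length(blk$cols) == 0L) next
    sums <- rowSums(df[, blk$cols, drop = FALSE])
    bad <- abs(sums - 100) > error_tol
    if (any(bad)) {
      stop(blk$what, " table fails closure for subject(s) ",
           paste(df$subject_id[bad], collapse = ", "),
           " (sums: ", paste(round(sums[bad], 2), collapse = ", "), ")",
           call. = FALSE)
    }
    off <- abs(sums - 100) > warn_tol
    if (any(off)) {
      warning(blk$what, " table sums outside 100 ± ", warn_tol,
              " for subject(s) ", paste(df$subject_id[off], collapse = ", "),
              call. = FALSE)
    }
    if (any(df[, blk$cols] < 0)) {
      stop(blk$what, " table contains negative percentages", call. = FALSE)
    }
  }
  attr(df, "fa_cols") <- fa_cols
  attr(df, "class_cols") <- class_cols
  class(df) <- unique(c("raft_cohort", class(df)))
  df
}

#' @export
#' @rdname as_raft_cohort
fa_cols <- function(cohort) attr(cohort, "fa_cols")

#' @export
#' @rdname as_raft_cohort
class_cols <- function(cohort) attr(cohort, "class_cols")

#' Extract one subject's fatty-acid profile as a named vector
#' @param cohort a `raft_cohort`.
#' @param subject_id subject identifier.
#' @return named numeric vector (mol% of total fatty acids + DMAs).
#' @export
fatty_acid_profile <- function(cohort, subject_id) {
  row <- cohort[cohort$subject_id == subject_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown subject_id: ", subject_id, call. = FALSE)
  unlist(row[, fa_cols(cohort), drop = FALSE])
}

#' Extract one subject's lipid-class profile as a named vector
#' @inheritParams fatty_acid_profile
#' @return named numeric vector (% of total lipid).
#' @export
lipid_class_profile <- function(cohort, subject_id) {
  row <- cohort[cohort$subject_id == subject_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown subject_id: ", subject_id, call. = FALSE)
  unlist(row[, class_cols(cohort), drop = FALSE])
}

#' Read / write a cohort CSV
#'
#' One row per subject; columns `subject_id, group, sex, age, pmd`, then
#' one column per fatty-acid token and per class token. UTF-8, comma
#' separated, `.` decimal. Closure is validated on read.
#'
#' @param path file path.
#' @inheritParams as_raft_cohort
#' @return [read_cohort()] returns a `raft_cohort`; [write_cohort()]
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path, warn_tol = 1, error_tol = 5) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_raft_cohort(df, warn_tol = warn_tol, error_tol = error_tol)
}

#' @param cohort a `raft_cohort` (or compatible data.frame).
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
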