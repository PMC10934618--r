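# Cross-protease comparison: selectivity profiles over HNE/PR3/CatG,
# fold changes against a reference compound, ranking, and the
# dual-inhibitor classification. Censored ("< bound") entries propagate as
# inequalities and never enter arithmetic.

validate_library <- function(library) {
  req <- c("compound_id", "enzyme", "kinact_over_KI", "censored")
  stopifnot(is.data.frame(library))
  missing_cols <- setdiff(req, names(library))
  if (length(missing_cols))
    stop("library is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- !library$censored & !is.finite(library$kinact_over_KI)
  if (any(bad))
    stop("non-censored entries must have numeric constants (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  if (any(library$censored & is.finite(library$kinact_over_KI)))
    stop("censored entries must not carry numeric constants", call. = FALSE)
  invisible(library)
}

library_value <- function(library, compound_id, enzyme) {
  row <- library[library$compound_id == compound_id &
                   library$enzyme == enzyme, , drop = FALSE]
  if (nrow(row) == 0L) return(NULL)
  if (nrow(row) > 1L)
    stop("duplicate library entry for compound ", compound_id, " / ", enzyme,
         call. = FALSE)
  if (row$censored)
    list(censored = TRUE, bound = row$bound)
  else
    list(censored = FALSE, value = row$kinact_over_KI)
}

#' Selectivity profile of one compound across the protease panel
#'
#' Collects the compound's per-enzyme entries (numeric constant or censored
#' bound), computes fold changes against a reference compound and pairwise
#' selectivity ratios wherever both members are numeric, and assigns a
#' label: an enzyme whose entry is censored at the inactivity bound counts
#' as inactive for that enzyme; a compound numeric on both elastase and
#' proteinase 3 within `dual_window`-fold of each other (and inactive on
#' cathepsin G) is a dual HNE/PR3 inhibitor; a compound numeric on exactly
#' one enzyme (or more than `dual_window`-fold apart) is labeled selective
#' for the stronger one; all-censored compounds are inactive.
#'
#' @param library Library data.frame as returned by
#'   [nsp_compound_library()] (columns `compound_id`, `enzyme`,
#'   `kinact_over_KI`, `censored`, `bound`).
#' @param compound_id Compound to profile.
#' @param reference_id Reference compound for fold changes (default `"27"`).
#' @param enzymes Panel order (default HNE, PR3, CatG).
#' @param dual_window Maximum fold difference for the "dual" call
#'   (default 10, the conventional selectivity cliff).
#' @return An object of class `selectivity_profile`: `compound_id`,
#'   `entries` (per-enzyme list), `reference_id`, `fold_vs_reference`
#'   (rounded; NA where either side is non-numeric), `pairwise` (full
#'   precision ratios), `label`.
#' @export
build_profile <- function(library, compound_id, reference_id = "27",
                          enzymes = c("HNE", "PR3", "CatG"),
                          dual_window = 10) {
  validate_library(library)
  if (!any(library$compound_id == reference_id & !library$censored))
    stop("reference compound ", reference_id,
         " has no numeric constant in the library", call. = FALSE)
  entries <- stats::setNames(
    lapply(enzymes, function(e) library_value(library, compound_id, e)),
    enzymes)
  if (all(vapply(entries, is.null, logical(1))))
    stop("compound ", compound_id, " has no entries in the library",
         call. = FALSE)

  num <- vapply(entries, function(x) {
    if (is.null(x) || x$censored) NA_real_ else x$value
  }, numeric(1))

  fold_ref <- stats::setNames(rep(NA_real_, length(enzymes)), enzymes)
  for (e in enzymes) {
    ref <- library_value(library, reference_id, e)
    if (!is.null(ref) && !ref$censored && is.finite(num[[e]]))
      fold_ref[[e]] <- fold_change(num[[e]], ref$value)
  }
  if (all(!is.finite(fold_ref)) && !any(is.finite(num))) {
    # no numeric entry anywhere: profile still valid, label inactive below
  }

  pairs <- utils::combn(enzymes, 2, simplify = FALSE)
  pairwise <- list()
  for (p in pairs) {
    if (is.finite(num[[p[1]]]) && is.finite(num[[p[2]]]))
      pairwise[[paste(p, collapse = "/")]] <-
        fold_change(num[[p[1]]], num[[p[2]]], rounded = FALSE)
  }

  h <- num[["HNE"]]; p3 <- num[["PR3"]]; cg <- num[["CatG"]]
  catg_quiet <- !is.finite(cg)
  label <- if (!any(is.finite(num))) {
    "inactive"
  } else if (is.finite(h) && is.finite(p3) &&
             max(h, p3) / min(h, p3) <= dual_window && catg_quiet) {
    "dual HNE/PR3"
  } else if (is.finite(h) && (!is.finite(p3) || h / p3 > dual_window) &&
             catg_quiet) {
    "HNE-selective"
  } else if (is.finite(p3) && (!is.finite(h) || p3 / h > dual_window) &&
             catg_quiet) {
    "PR3-selective"
  } else {
    "other"
  }

  structure(list(compound_id = compound_id, entries = entries,
                 reference_id = reference_id, fold_vs_reference = fold_ref,
                 pairwise = pairwise, dual_window = dual_window,
                 label = label),
            class = "selectivity_profile")
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat(sprintf("<selectivity_profile> compound %s: %s\n", x$compound_id,
              x$label))
  for (e in names(x$entries)) {
    v <- x$entries[[e]]
    txt <- if (is.null(v)) "not measured"
    else if (v$censored) sprintf("< %g M^-1 s^-1 (inactive)", v$bound)
    else sprintf("%g M^-1 s^-1", v$value)
    fold <- x$fold_vs_reference[[e]]
    cat(sprintf("  %-5s %s%s\n", e, txt,
                if (is.finite(fold))
                  sprintf("  [%.1fx vs %s]", fold, x$reference_id) else ""))
  }
  invisible(x)
}

#' Rank a library by potency against one enzyme
#'
#' Stable descending sort by the second-order constant; censored (bounded)
#' entries are listed last, and ties break lexicographically by compound id.
#'
#' @param library Library data.frame (see [build_profile()]).
#' @param enzyme Enzyme to rank by.
#' @return data.frame ordered by rank with columns `rank`, `compound_id`,
#'   `kinact_over_KI`, `censored`, `bound`, `display` (constant or
#'   `"<bound"`).
#' @export
rank_library <- function(library, enzyme) {
  validate_library(library)
  d <- library[library$enzyme == enzyme, , drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(rank = integer(0), compound_id = character(0),
                      kinact_over_KI = numeric(0), censored = logical(0),
                      bound = numeric(0), display = character(0),
                      stringsAsFactors = FALSE))
  num <- d[!d$censored, , drop = FALSE]
  cen <- d[d$censored, , drop = FALSE]
  num <- num[order(-num$kinact_over_KI, num$compound_id), , drop = FALSE]
  cen <- cen[order(cen$compound_id), , drop = FALSE]
  out <- rbind(num, cen)
  data.frame(rank = seq_len(nrow(out)),
             compound_id = out$compound_id,
             kinact_over_KI = out$kinact_over_KI,
             censored = out$censored,
             bound = out$bound,
             display = ifelse(out$censored, paste0("<", out$bound),
                              format(out$kinact_over_KI, scientific = FALSE,
                                     trim = TRUE)),
             stringsAsFactors = FALSE)
}

#' Fold-change table against a reference compound
#'
#' For every enzyme where the reference constant is numeric, reports each
#' compound's fold change versus the reference (rounded for display, full
#' precision alongside). Censored entries are carried through as their
#' bound, never as numbers.
#'
#' @param library Library data.frame (see [build_profile()]).
#' @param reference_id Reference compound (default `"27"`).
#' @return data.frame with columns `compound_id`, `enzyme`,
#'   `kinact_over_KI`, `censored`, `fold`, `fold_exact`, `display`.
#' @export
#' @examples
#' lib <- nsp_compound_library()
#' subset(fold_table(lib), compound_id %in% c("78", "111", "113"))
fold_table <- function(library, reference_id = "27") {
  validate_library(library)
  refs <- library[library$compound_id == reference_id & !library$censored, ,
                  drop = FALSE]
  if (nrow(refs) == 0L)
    stop("reference compound ", reference_id,
         " has no numeric constant in the library", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(refs))) {
    e <- refs$enzyme[i]
    refval <- refs$kinact_over_KI[i]
    d <- library[library$enzyme == e & library$compound_id != reference_id, ,
                 drop = FALSE]
    if (nrow(d) == 0L) next
    fold <- ifelse(d$censored, NA_real_,
                   fold_change(d$kinact_over_KI, refval))
    fold_exact <- ifelse(d$censored, NA_real_,
                         fold_change(d$kinact_over_KI, refval,
                                     rounded = FALSE))
    out[[e]] <- data.frame(
      compound_id = d$compound_id, enzyme = e,
      kinact_over_KI = d$kinact_over_KI, censored = d$censored,
      fold = fold, fold_exact = fold_exact,
      display = ifelse(d$censored, paste0("<", d$bound),
                       sprintf("%.1fx", fold)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    stop("no comparable compounds for reference ", reference_id,
         call. = FALSE)
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
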