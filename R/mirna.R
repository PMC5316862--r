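# Count-column conventions: control samples are columns matching ^control_,
# disease samples ^disease_. Group means are per-miRNA means across samples.
.group_cols <- function(table, group = c("control", "disease")) {
  group <- match.arg(group)
  cols <- grep(paste0("^", group, "_"), names(table), value = TRUE)
  if (length(cols) == 0) stop("no ", group, " count columns (", group, "_*)")
  cols
}

.group_means <- function(table, group) {
  rowMeans(as.matrix(table[, .group_cols(table, group), drop = FALSE]))
}

#' Group miRNAs into seed families
#'
#' miRNAs with identical seeds -- nucleotides 2 to 8 of the mature sequence
#' -- share a broadly overlapping target repertoire and are grouped into one
#' family. The family id is the seed string itself unless a name map is
#' supplied. Sequences shorter than 8 nt cannot be assigned and get NA.
#'
#' @param table A data.frame with columns \code{mirna_id} and
#'   \code{mature_sequence} (T is read as U, case-insensitive).
#' @param name_map Optional named character vector mapping seed 7-mers to
#'   family names (e.g. \code{c(AAAGUGC = "miR-17")}).
#' @return The table with columns \code{seed_7mer} and \code{family_id}
#'   added.
#' @export
#' @examples
#' tab <- data.frame(mirna_id = c("miR-17-5p", "miR-106b-5p"),
#'                   mature_sequence = c("CAAAGUGCUUACAGUGCAGGUAG",
#'                                       "UAAAGUGCUGACAGUGCAGAU"))
#' assign_seed_family(tab)$family_id
assign_seed_family <- function(table, name_map = NULL) {
  stopifnot(is.data.frame(table),
            all(c("mirna_id", "mature_sequence") %in% names(table)))
  seqs <- chartr("Tt", "Uu", toupper(table$mature_sequence))
  seed <- ifelse(nchar(seqs) >= 8, substr(seqs, 2, 8), NA_character_)
  table$seed_7mer <- seed
  table$family_id <- seed
  if (!is.null(name_map)) {
    hit <- !is.na(seed) & seed %in% names(name_map)
    table$family_id[hit] <- unname(name_map[seed[hit]])
  }
  table
}

#' Cumulative fold change of one seed family
#'
#' The family-level fold change is the fold change of the family's pooled
#' signal: \code{log2(sum of member disease means / sum of member control
#' means)}, over either all expressed members or only those flagged
#' significant. Pooling counts before the ratio keeps the statistic
#' well-defined when members differ in abundance; the alternative reading
#' (summing per-member log2 fold changes) is available as
#' \code{method = "sum_log2"}.
#'
#' @param table A data.frame with \code{family_id} (from
#'   [assign_seed_family()]), count columns, and (for
#'   \code{members = "significant_only"}) a logical \code{significant}
#'   column.
#' @param family_id Which family to aggregate.
#' @param members \code{"all_expressed"} (default) or
#'   \code{"significant_only"}.
#' @param method \code{"pooled"} (default) or \code{"sum_log2"}.
#' @return A single log2 fold change; NA (with a warning) when the family
#'   has no eligible members.
#' @export
#' @examples
#' tab <- data.frame(mirna_id = c("a", "b"), family_id = "F",
#'                   control_1 = c(100, 100), disease_1 = c(300, 100),
#'                   significant = c(TRUE, FALSE))
#' family_cumulative_fold_change(tab, "F")                      # log2(400/200) = 1
#' family_cumulative_fold_change(tab, "F", "significant_only")  # log2(300/100)
family_cumulative_fold_change <- function(table, family_id,
                                          members = c("all_expressed",
                                                      "significant_only"),
                                          method = c("pooled", "sum_log2")) {
  members <- match.arg(members)
  method <- match.arg(method)
  stopifnot("family_id" %in% names(table))
  sel <- !is.na(table$family_id) & table$family_id == family_id
  if (members == "significant_only") {
    stopifnot("significant" %in% names(table))
    sel <- sel & table$significant
  }
  if (!any(sel)) {
    warning("family '", family_id, "' has no eligible members")
    return(NA_real_)
  }
  sub <- table[sel, , drop = FALSE]
  mc <- .group_means(sub, "control")
  md <- .group_means(sub, "disease")
  if (method == "pooled") {
    if (sum(mc) <= 0) stop("zero control total for family '", family_id, "'")
    log2(sum(md) / sum(mc))
  } else {
    if (any(mc <= 0)) stop("zero control mean for a member of '",
                           family_id, "'")
    sum(log2(md / mc))
  }
}

#' Percentage contribution of one family to the total miRNA pool
#'
#' 100 times the family's summed mean counts divided by the summed mean
#' counts of every miRNA in the table, within one group. Families absent
#' from the table contribute 0.
#'
#' @param table A data.frame with \code{family_id} and count columns.
#' @param family_id Which family.
#' @param group \code{"control"} or \code{"disease"}.
#' @return A percentage in `[0, 100]`.
#' @export
family_pool_contribution <- function(table, family_id,
                                     group = c("control", "disease")) {
  group <- match.arg(group)
  stopifnot("family_id" %in% names(table))
  m <- .group_means(table, group)
  total <- sum(m)
  if (total <= 0) stop("zero total counts in group '", group, "'")
  sel <- !is.na(table$family_id) & table$family_id == family_id
  100 * sum(m[sel]) / total
}

#' Summarize every seed family in a table
#'
#' @param table A data.frame with \code{family_id}, \code{seed_7mer},
#'   count columns and a \code{significant} column.
#' @return A data.frame with one row per family: member counts, cumulative
#'   log2 fold changes over significant members
#'   (\code{cumulative_log2_fc_sig}, NA when none are significant) and all
#'   members (\code{cumulative_log2_fc_all}), and the percentage of the
#'   miRNA pool in each group.
#' @export
summarize_seed_families <- function(table) {
  stopifnot(all(c("family_id", "significant") %in% names(table)))
  fams <- unique(table$family_id[!is.na(table$family_id)])
  out <- do.call(rbind, lapply(fams, function(f) {
    sel <- !is.na(table$family_id) & table$family_id == f
    n_sig <- sum(table$significant[sel])
    data.frame(
      family_id = f,
      seed_7mer = if ("seed_7mer" %in% names(table))
        table$seed_7mer[sel][1] else NA_character_,
      n_members_total = sum(sel),
      n_members_significant = n_sig,
      cumulative_log2_fc_sig = if (n_sig > 0)
        family_cumulative_fold_change(table, f, "significant_only")
        else NA_real_,
      cumulative_log2_fc_all = family_cumulative_fold_change(table, f),
      pool_pct_control = family_pool_contribution(table, f, "control"),
      pool_pct_disease = family_pool_contribution(table, f, "disease"))
  }))
  rownames(out) <- NULL
  out
}

#' Squared correlation of per-miRNA fold changes between two models
#'
#' Pearson R-squared over the miRNAs common to both named vectors. At least
#' three shared miRNAs with finite values are required; zero variance in
#' either vector gives NA with a warning.
#'
#' @param fc_a,fc_b Named numeric vectors of per-miRNA log2 fold changes.
#' @return R-squared in `[0, 1]`, or NA.
#' @export
#' @examples
#' cross_model_correlation(c(a = 1, b = 2, c = 3), c(a = 1, b = 3, c = 2))
cross_model_correlation <- function(fc_a, fc_b) {
  stopifnot(!is.null(names(fc_a)), !is.null(names(fc_b)))
  shared <- intersect(names(fc_a), names(fc_b))
  a <- fc_a[shared]; b <- fc_b[shared]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3)
    stop("need at least 3 shared miRNAs with finite fold changes")
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a fold-change vector; R^2 undefined")
    return(NA_real_)
  }
  unname(cor(a, b)^2)
}
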