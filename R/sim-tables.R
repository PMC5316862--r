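#' Planted miRNA expression model
#'
#' Describes a set of miRNA seed families with known (planted) family-level
#' log2 fold changes between a control and a disease group, used by
#' [generate_expression_table()] to emit count tables against which the
#' family-aggregation statistics can be scored.
#'
#' @param families A data.frame with columns \code{family_id},
#'   \code{seed_7mer} (7-nt seed, positions 2-8 of the mature sequence),
#'   \code{n_members} (members per family) and \code{planted_log2_fc}.
#'   An optional list-column \code{member_ids} overrides the auto-generated
#'   member names; member ids must be disjoint across families.
#' @param baseline_counts Mean control count per miRNA (> 0); recycled across
#'   members.
#' @param dispersion Negative-binomial overdispersion (>= 0); 0 degenerates
#'   to deterministic means so planted values are recovered exactly.
#' @param n_control,n_disease Samples per group (each >= 1).
#' @param seed Integer seed.
#'
#' @return An object of class \code{planted_expression_model}.
#' @export
planted_expression_model <- function(families, baseline_counts = 500,
                                     dispersion = 0,
                                     n_control = 3, n_disease = 3,
                                     seed = 1L) {
  stopifnot(is.data.frame(families),
            all(c("family_id", "seed_7mer", "n_members", "planted_log2_fc")
                %in% names(families)))
  if (any(nchar(families$seed_7mer) != 7))
    stop("seed_7mer entries must be exactly 7 nt")
  if (anyDuplicated(families$family_id))
    stop("family_id values must be unique")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_control < 1 || n_disease < 1)
    stop("n_control and n_disease must each be >= 1")
  if (any(baseline_counts <= 0)) stop("baseline_counts must be > 0")
  if (!is.null(families$member_ids)) {
    ids <- unlist(families$member_ids)
    if (anyDuplicated(ids)) stop("member_ids must be disjoint across families")
    if (any(lengths(families$member_ids) != families$n_members))
      stop("member_ids lengths must match n_members")
  }
  structure(list(families = families, baseline_counts = baseline_counts,
                 dispersion = dispersion,
                 n_control = as.integer(n_control),
                 n_disease = as.integer(n_disease), seed = seed),
            class = "planted_expression_model")
}

.random_mature_sequence <- function(seed_7mer, length = 22) {
  nt <- c("A", "C", "G", "U")
  s <- sample(nt, length, replace = TRUE)
  s[2:8] <- strsplit(seed_7mer, "")[[1]]
  paste(s, collapse = "")
}

#' Generate a miRNA differential-expression count table
#'
#' Draws per-miRNA counts from a negative-binomial mean/dispersion model in
#' which all members of a family share the planted fold change: control mean
#' is the baseline, disease mean is baseline times \code{2^planted_log2_fc}.
#' With \code{dispersion = 0} counts equal their means exactly. Mature
#' sequences are random with positions 2-8 fixed to the family seed.
#'
#' @param model A [planted_expression_model()].
#' @return A data.frame with columns \code{mirna_id}, \code{mature_sequence},
#'   \code{control_1..n}, \code{disease_1..m}, \code{log2_fc} (per-miRNA
#'   observed log2 ratio of group means) and \code{significant} (TRUE for
#'   members of families with a non-zero planted fold change).
#' @export
#' @examples
#' fams <- data.frame(family_id = "miR-17", seed_7mer = "AAAGUGC",
#'                    n_members = 3, planted_log2_fc = 1)
#' tab <- generate_expression_table(planted_expression_model(fams))
generate_expression_table <- function(model) {
  stopifnot(inherits(model, "planted_expression_model"))
  fam <- model$families
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(model$seed)

  rows <- lapply(seq_len(nrow(fam)), function(i) {
    n <- fam$n_members[i]
    ids <- if (!is.null(fam$member_ids)) fam$member_ids[[i]] else
      paste0(fam$family_id[i], "-", letters[seq_len(n)])
    data.frame(mirna_id = ids,
               family = fam$family_id[i],
               seed_7mer = fam$seed_7mer[i],
               planted = fam$planted_log2_fc[i])
  })
  tab <- do.call(rbind, rows)
  n_mirna <- nrow(tab)
  base <- rep_len(model$baseline_counts, n_mirna)
  mu_ctrl <- base
  mu_dis <- base * 2^tab$planted

  draw <- function(mu, n_samples) {
    m <- if (model$dispersion == 0)
      matrix(rep(mu, n_samples), nrow = length(mu))
    else
      matrix(rnbinom(length(mu) * n_samples, mu = rep(mu, n_samples),
                     size = 1 / model$dispersion), nrow = length(mu))
    m
  }
  ctrl <- draw(mu_ctrl, model$n_control)
  dis <- draw(mu_dis, model$n_disease)
  colnames(ctrl) <- paste0("control_", seq_len(model$n_control))
  colnames(dis) <- paste0("disease_", seq_len(model$n_disease))

  seqs <- vapply(tab$seed_7mer, .random_mature_sequence, character(1))
  mc <- rowMeans(ctrl); md <- rowMeans(dis)
  out <- data.frame(mirna_id = tab$mirna_id, mature_sequence = unname(seqs),
                    ctrl, dis,
                    log2_fc = ifelse(mc > 0 & md > 0, log2(md / mc), NA_real_),
                    significant = tab$planted != 0)
  rownames(out) <- NULL
  out
}

#' Generate a miPSA Ct table with a planted polysome displacement
#'
#' Emits qPCR cycle-threshold values for a target and a reference gene in
#' treated and control samples such that the delta-delta-Ct estimator
#' ([mipsa_displacement()]) applied to noiseless output returns exactly
#' \code{true_displacement_log2}. A positive displacement means the target
#' needs more cycles in the treated polysome fraction, i.e. it was lost from
#' that fraction. \code{reference_shift} moves the reference gene's Ct in
#' both conditions equally and must cancel in the estimator.
#'
#' @param true_displacement_log2 Planted displacement, log2 units.
#' @param reference_shift Cycles added to the reference gene in both
#'   conditions.
#' @param ct_noise_sd Gaussian noise on each Ct value, cycles (>= 0).
#' @param n_replicates Replicates per gene x condition.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{gene} ("target"/"reference"),
#'   \code{condition} ("treated"/"control"), \code{replicate}, \code{ct}.
#' @export
generate_mipsa_table <- function(true_displacement_log2, reference_shift = 0,
                                 ct_noise_sd = 0, n_replicates = 3,
                                 seed = 1L) {
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  base_target <- 20; base_reference <- 18
  grid <- expand.grid(gene = c("target", "reference"),
                      condition = c("treated", "control"),
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  ct <- ifelse(grid$gene == "target",
               base_target +
                 ifelse(grid$condition == "treated", true_displacement_log2, 0),
               base_reference + reference_shift)
  grid$ct <- ct + if (ct_noise_sd > 0)
    rnorm(nrow(grid), 0, ct_noise_sd) else 0
  grid
}

#' Generate a BOFA oxygen-consumption trace with known ATP-linked OCR
#'
#' Emits a Seahorse-style trace of the basal / oligomycin / FCCP /
#' antimycin-A+rotenone injection protocol, parameterized so that
#' [atp_linked_ocr()] applied to noiseless output recovers
#' \code{atp_linked} exactly (post-oligomycin OCR = basal - atp_linked).
#'
#' @param basal Basal OCR, pmol O2/min.
#' @param atp_linked Planted ATP-linked OCR (basal minus post-oligomycin).
#' @param spare FCCP-phase OCR above basal (maximal respiration reserve).
#' @param non_mitochondrial OCR remaining after antimycin-A/rotenone.
#' @param n_per_phase Measurements per phase.
#' @param noise_sd Gaussian noise per measurement (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns \code{time} (minutes), \code{phase}
#'   (basal, oligomycin, FCCP, antimycinA_rotenone, in BOFA order),
#'   \code{ocr}.
#' @export
generate_ocr_trace <- function(basal = 100, atp_linked = 60, spare = 50,
                               non_mitochondrial = 10, n_per_phase = 3,
                               noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  phases <- c("basal", "oligomycin", "FCCP", "antimycinA_rotenone")
  level <- c(basal, basal - atp_linked, basal + spare, non_mitochondrial)
  out <- data.frame(
    time = seq_len(4 * n_per_phase) * 8,
    phase = rep(phases, each = n_per_phase),
    ocr = rep(level, each = n_per_phase))
  if (noise_sd > 0) out$ocr <- out$ocr + rnorm(nrow(out), 0, noise_sd)
  out
}
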