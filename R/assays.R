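#' Polysome displacement by the delta-delta-Ct method
#'
#' Quantifies the loss of a miRNA from the assayed polysome fraction under
#' treatment. For each condition the target's mean Ct is normalized to the
#' reference gene (\eqn{\Delta Ct = \bar{Ct}_{target} - \bar{Ct}_{reference}});
#' the displacement is \eqn{\Delta Ct_{treated} - \Delta Ct_{control}}, in
#' log2 units. Positive values mean the target needs more cycles relative to
#' the reference in the treated fraction, i.e. it was displaced from that
#' fraction. A uniform shift of the reference gene across both conditions
#' cancels exactly.
#'
#' @param ct_table A data.frame with columns \code{gene} (values
#'   \code{"target"} and \code{"reference"}), \code{condition} (values
#'   \code{"treated"} and \code{"control"}) and \code{ct} (cycles, > 0).
#' @return The log2 displacement (a single number).
#' @export
#' @examples
#' tab <- data.frame(gene = c("target", "reference", "target", "reference"),
#'                   condition = c("treated", "treated", "control", "control"),
#'                   ct = c(21, 18, 20, 18))
#' mipsa_displacement(tab)  # (21 - 18) - (20 - 18) = +1
mipsa_displacement <- function(ct_table) {
  stopifnot(is.data.frame(ct_table),
            all(c("gene", "condition", "ct") %in% names(ct_table)))
  if (any(ct_table$ct <= 0)) stop("Ct values must be > 0")
  cell_mean <- function(gene, condition) {
    sel <- ct_table$gene == gene & ct_table$condition == condition
    if (!any(sel)) stop("missing Ct values for ", gene, " x ", condition)
    mean(ct_table$ct[sel])
  }
  d_treated <- cell_mean("target", "treated") - cell_mean("reference", "treated")
  d_control <- cell_mean("target", "control") - cell_mean("reference", "control")
  d_treated - d_control
}

#' ATP-linked oxygen consumption rate
#'
#' From a BOFA (basal, oligomycin, FCCP, antimycin-A/rotenone) trace, the
#' respiration devoted to ATP synthesis is the drop in OCR when ATP synthase
#' is blocked: mean basal OCR minus mean post-oligomycin OCR. A negative
#' result (post-oligomycin above basal) is returned as-is with a warning,
#' since it usually indicates a failed injection.
#'
#' @param trace A data.frame with columns \code{phase} (containing at least
#'   one \code{"basal"} and one \code{"oligomycin"} measurement) and
#'   \code{ocr} (pmol O2/min).
#' @return ATP-linked OCR in pmol O2/min.
#' @export
#' @examples
#' tr <- data.frame(phase = c("basal", "oligomycin"), ocr = c(100, 40))
#' atp_linked_ocr(tr)  # 60
atp_linked_ocr <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("phase", "ocr") %in% names(trace)))
  basal <- trace$ocr[trace$phase == "basal"]
  oligo <- trace$ocr[trace$phase == "oligomycin"]
  if (length(basal) == 0) stop("missing basal phase")
  if (length(oligo) == 0) stop("missing oligomycin phase")
  out <- mean(basal) - mean(oligo)
  if (out < 0)
    warning("post-oligomycin OCR exceeds basal; ATP-linked OCR is negative")
  out
}
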