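#' Relative abundance from a threshold cycle
#'
#' `2^-Ct`, the standard exponential-amplification transform (efficiency
#' fixed at 2, no efficiency correction).
#'
#' @param ct_mean Mean threshold cycle(s); finite.
#' @return Relative abundance(s).
#' @export
ct_abundance <- function(ct_mean) {
  if (any(!is.finite(ct_mean))) stop("ct_abundance: Ct must be finite")
  2^(-ct_mean)
}

#' Pull-down relative enrichment
#'
#' Input-normalized pull-down abundance, divided by the same ratio for
#' the negative control (e.g. a no-ligand pull-down):
#' `[2^-Ct(pd) / 2^-Ct(input)] / [2^-Ct(ctrl pd) / 2^-Ct(ctrl input)]`.
#' Invariant under adding a constant to every Ct.
#'
#' @param pd_ct,input_ct Mean Cts of the pull-down and its input control.
#' @param ctrl_pd_ct,ctrl_input_ct Mean Cts of the negative-control
#'   pull-down and its input.
#' @return Fold enrichment (> 0).
#' @examples
#' relative_enrichment(20, 18, 25, 18)  # 32
#' @export
relative_enrichment <- function(pd_ct, input_ct, ctrl_pd_ct, ctrl_input_ct) {
  cts <- c(pd_ct, input_ct, ctrl_pd_ct, ctrl_input_ct)
  if (any(!is.finite(cts)))
    stop("relative_enrichment: all four mean Cts must be finite ",
         "(missing control?)")
  (ct_abundance(pd_ct) / ct_abundance(input_ct)) /
    (ct_abundance(ctrl_pd_ct) / ct_abundance(ctrl_input_ct))
}

#' Expression fold change by the 2^-ddCt method
#'
#' `2^-[(Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,mock - Ct_ref,mock)]`, i.e. target expression normalized
#' to a reference gene and expressed relative to the mock condition.
#'
#' @param target_ct_treated,ref_ct_treated Mean Cts under treatment.
#' @param target_ct_mock,ref_ct_mock Mean Cts under mock.
#' @return Fold change (> 0).
#' @export
ddct_expression <- function(target_ct_treated, ref_ct_treated,
                            target_ct_mock, ref_ct_mock) {
  cts <- c(target_ct_treated, ref_ct_treated, target_ct_mock, ref_ct_mock)
  if (any(!is.finite(cts))) stop("ddct_expression: Cts must be finite")
  ddct <- (target_ct_treated - ref_ct_treated) -
    (target_ct_mock - ref_ct_mock)
  2^(-ddct)
}

#' Average replicate Cts in a tidy Ct table
#'
#' Replicates are averaged on the Ct scale (arithmetic mean of cycles)
#' before any exponential transform. Non-finite Cts (undetermined wells)
#' are dropped with a warning by default, or substituted with a ceiling
#' value.
#'
#' @param ct_df data.frame with columns `sample`, `condition`, `target`,
#'   `replicate`, `ct`.
#' @param undetermined `"drop"` (default) or a numeric ceiling Ct to
#'   substitute.
#' @return data.frame with one row per (sample, condition, target):
#'   `ct_mean`, `n_replicates`.
#' @export
average_ct <- function(ct_df, undetermined = "drop") {
  need <- c("sample", "condition", "target", "replicate", "ct")
  if (!all(need %in% names(ct_df)))
    stop("average_ct: need columns ", paste(need, collapse = ", "))
  bad <- !is.finite(ct_df$ct)
  if (any(bad)) {
    if (identical(undetermined, "drop")) {
      warning("average_ct: dropping ", sum(bad), " undetermined Ct value(s)")
      ct_df <- ct_df[!bad, , drop = FALSE]
    } else if (is.numeric(undetermined)) {
      ct_df$ct[bad] <- undetermined
    } else stop("average_ct: 'undetermined' must be \"drop\" or a numeric ceiling")
  }
  if (nrow(ct_df) == 0) stop("average_ct: no usable Ct values")
  agg <- aggregate(ct ~ sample + condition + target, data = ct_df, FUN = mean)
  cnt <- aggregate(ct ~ sample + condition + target, data = ct_df, FUN = length)
  names(agg)[names(agg) == "ct"] <- "ct_mean"
  agg$n_replicates <- cnt$ct
  agg
}

#' Per-target relative enrichment from a tidy Ct table
#'
#' For each target, averages replicate Cts per condition and computes
#' the input- and negative-control-normalized fold enrichment. Expects
#' conditions `pulldown`, `input`, `control_pulldown`, `control_input`.
#'
#' @inheritParams average_ct
#' @return data.frame with columns `target`, `fold_enrichment`.
#' @export
enrichment_table <- function(ct_df, undetermined = "drop") {
  avg <- average_ct(ct_df, undetermined)
  out <- lapply(split(avg, avg$target), function(d) {
    get1 <- function(cond) {
      v <- d$ct_mean[d$condition == cond]
      if (length(v) != 1L)
        stop("enrichment_table: target '", d$target[1L],
             "' needs exactly one '", cond, "' condition")
      v
    }
    data.frame(target = d$target[1L],
               fold_enrichment = relative_enrichment(
                 get1("pulldown"), get1("input"),
                 get1("control_pulldown"), get1("control_input")))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @importFrom stats aggregate
NULL
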