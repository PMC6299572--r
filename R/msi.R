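#' Classify one sample's microsatellite panel
#'
#' A tumor is microsatellite-instable (MSI) if at least `threshold_fraction`
#' of its informative microsatellite markers are unstable; the default
#' panel is the five Bethesda markers (D2S123, D5S346, D17S250, BAT25,
#' BAT26) plus BAT40, and the default threshold is 30\% inclusive, so 2/6
#' unstable markers already qualify as MSI.
#'
#' Failed markers are excluded from the denominator by default (a failed
#' assay carries no instability information); set
#' `failed_as_stable = TRUE` to count them as stable instead.
#'
#' @param calls character vector of marker calls, each one of "stable",
#'   "unstable", "failed"
#' @param threshold_fraction inclusive MSI threshold (default 0.30)
#' @param failed_as_stable if TRUE, failed markers enter the denominator
#'   as stable
#' @return list: `unstable_fraction`, `status` ("MSI" or "MSS"),
#'   `n_informative`
#' @examples
#' classify_msi(c("unstable", "unstable", rep("stable", 4)))$status # MSI
#' classify_msi(c("unstable", rep("stable", 5)))$status             # MSS
#' @export
classify_msi <- function(calls, threshold_fraction = 0.30,
                         failed_as_stable = FALSE) {
  bad <- setdiff(unique(calls), c("stable", "unstable", "failed"))
  if (length(bad))
    stop("unknown marker call(s): ", paste(bad, collapse = ", "))
  if (failed_as_stable) calls[calls == "failed"] <- "stable"
  informative <- calls != "failed"
  if (!any(informative))
    stop("all markers failed; cannot classify")
  frac <- sum(calls == "unstable") / sum(informative)
  list(unstable_fraction = frac,
       status = if (frac >= threshold_fraction) "MSI" else "MSS",
       n_informative = sum(informative))
}

#' MSI-type every sample of a panel table
#'
#' @param panel data.frame with a `sample_id` column and one column per
#'   microsatellite marker (calls "stable"/"unstable"/"failed")
#' @param threshold_fraction inclusive MSI threshold
#' @param failed_as_stable see [classify_msi()]
#' @return data.frame: `sample_id`, `unstable_fraction`, `status`
#' @export
msi_type_cohort <- function(panel, threshold_fraction = 0.30,
                            failed_as_stable = FALSE) {
  marker_cols <- setdiff(names(panel), "sample_id")
  res <- lapply(seq_len(nrow(panel)), function(i)
    classify_msi(as.character(unlist(panel[i, marker_cols])),
                 threshold_fraction, failed_as_stable))
  data.frame(sample_id = panel$sample_id,
             unstable_fraction = vapply(res, `[[`, numeric(1),
                                        "unstable_fraction"),
             status = vapply(res, `[[`, character(1), "status"),
             stringsAsFactors = FALSE)
}
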