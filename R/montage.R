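#' Standard 32-channel scalp montage
#'
#' The electrode montage used throughout the package: 32 Ag/AgCl scalp
#' positions of the extended 10-20 system. Cluster definitions for every ERP
#' component resolve against these labels, and the synthetic generator places
#' its component topographies on them.
#'
#' @return Character vector of 32 channel labels.
#' @export
standardMontage <- function() {
  c("FP1", "FPZ", "FP2", "F7", "F3", "FZ", "F4", "F8",
    "FT7", "FC3", "FCZ", "FC4", "FT8", "T7", "C3", "CZ",
    "C4", "T8", "TP7", "CP3", "CPZ", "CP4", "TP8", "P7",
    "P3", "PZ", "P4", "P8", "POZ", "O1", "OZ", "O2")
}

#' Electrode clusters for ERP quantification
#'
#' Named electrode sets over which component amplitudes are averaged:
#' \describe{
#'   \item{frontocentral}{F3, FZ, F4, FC3, FCZ, FC4, C3, CZ, C4 -- FRN.}
#'   \item{centroparietal}{CP3, CPZ, CP4, P3, PZ, P4, POZ -- P3.}
#'   \item{visual}{P7, P3, PZ, P4, P8, POZ, O1, OZ, O2 -- P1 and N1.}
#'   \item{spn_left / spn_central / spn_right}{the three laterality columns
#'     of the 9-channel SPN cluster (FC3/C3/CP3, FCZ/CZ/CPZ, FC4/C4/CP4).}
#' }
#'
#' @return Named list of character vectors, all subsets of
#'   [standardMontage()].
#' @export
erpClusters <- function() {
  list(
    frontocentral = c("F3", "FZ", "F4", "FC3", "FCZ", "FC4", "C3", "CZ", "C4"),
    centroparietal = c("CP3", "CPZ", "CP4", "P3", "PZ", "P4", "POZ"),
    visual = c("P7", "P3", "PZ", "P4", "P8", "POZ", "O1", "OZ", "O2"),
    spn_left = c("FC3", "C3", "CP3"),
    spn_central = c("FCZ", "CZ", "CPZ"),
    spn_right = c("FC4", "C4", "CP4")
  )
}
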