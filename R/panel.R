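# The tyrosine-kinase gene universe and the published 13-gene signature.

#' The 86-gene tyrosine kinase panel
#'
#' A default gene universe of 86 human tyrosine kinase symbols used as the
#' candidate panel for signature discovery and as the sampling universe for
#' the resampling null. The panel contains the 13 signature genes reported
#' in triple-negative breast cancer (EPH receptors EPHA1, EPHA4, EPHA7,
#' EPHB4, EPHB6; SRC-family kinases SRC and FYN; immune kinases ITK and
#' ZAP70; and FLT1, ALK, ERBB4, PTK2B) together with 73 further receptor and
#' cytoplasmic tyrosine kinases of the human kinome.
#'
#' @return Character vector of 86 unique gene symbols, sorted.
#' @export
tkPanel <- function() {
  panel <- c(
    # published signature genes
    "EPHA1", "EPHA4", "EPHA7", "EPHB4", "EPHB6", "SRC", "FYN", "ITK",
    "ZAP70", "FLT1", "ALK", "ERBB4", "PTK2B",
    # remaining receptor and cytoplasmic tyrosine kinases
    "ABL1", "ABL2", "AATK", "AXL", "BLK", "BMX", "BTK", "CSF1R", "CSK",
    "DDR1", "DDR2", "EGFR", "EPHA2", "EPHA3", "EPHA5", "EPHA6", "EPHA8",
    "EPHB1", "EPHB2", "EPHB3", "ERBB2", "ERBB3", "FER", "FES", "FGFR1",
    "FGFR2", "FGFR3", "FGFR4", "FGR", "FLT3", "FLT4", "FRK", "HCK",
    "IGF1R", "INSR", "JAK1", "JAK2", "JAK3", "KDR", "KIT", "LCK", "LTK",
    "LYN", "MATK", "MERTK", "MET", "MST1R", "MUSK", "NTRK1", "NTRK2",
    "NTRK3", "PDGFRA", "PDGFRB", "PTK2", "PTK6", "PTK7", "RET", "ROR1",
    "ROR2", "ROS1", "RYK", "SRMS", "STYK1", "SYK", "TEC", "TEK", "TIE1",
    "TNK1", "TNK2", "TXK", "TYK2", "TYRO3", "YES1"
  )
  stopifnot(!anyDuplicated(panel), length(panel) == 86L)
  sort(panel)
}

#' The published 13-gene signature (gene list and effect directions)
#'
#' The reported triple-negative breast cancer signature as a fixture:
#' gene symbols with the published direction of univariate association with
#' disease-free survival (+1 = higher expression, shorter DFS; -1 = higher
#' expression, longer DFS). Coefficients were not published, so none are
#' carried; use [stepwiseAic()] on your own cohort to fit coefficients, or
#' fit the listed genes directly with [coxFit()].
#'
#' @return A data.frame with columns `gene` and `direction`.
#' @export
publishedSignature <- function() {
  data.frame(
    gene = c("ALK", "FLT1", "EPHA4", "EPHA7", "EPHB4",
             "EPHA1", "EPHB6", "SRC", "FYN", "ITK", "ZAP70", "ERBB4",
             "PTK2B"),
    direction = c(rep(1L, 5L), rep(-1L, 8L)),
    stringsAsFactors = FALSE
  )
}
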