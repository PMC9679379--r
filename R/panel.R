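#' Default DNA 5mC regulator panel
#'
#' The 20-gene panel of 5-methylcytosine machinery commonly profiled in tumor
#' cohorts: the three writers (DNMT1/3A/3B) that deposit the mark, the three
#' erasers (TET1/2/3) that oxidize it away, and fourteen readers — methyl-CpG
#' binding proteins (MBD1-4, MECP2), zinc-finger readers (ZBTB4/33/38), the
#' UHRF hemimethylation readers and the base-excision glycosylases
#' (UNG, TDG, NTHL1, SMUG1) that process the mark.
#'
#' The panel is a plain tibble, not a constant baked into any algorithm: pass
#' your own `gene`/`role` table anywhere a panel is accepted.
#'
#' @return tibble with columns `gene` and `role` (`writer`, `eraser`, `reader`).
#' @export
default_regulator_panel <- function() {
  tibble(
    gene = c("DNMT1", "DNMT3A", "DNMT3B",
             "TET1", "TET2", "TET3",
             "ZBTB33", "ZBTB38", "ZBTB4", "MBD1", "MBD2", "MBD3", "MBD4",
             "MECP2", "UNG", "TDG", "NTHL1", "SMUG1", "UHRF1", "UHRF2"),
    role = c(rep("writer", 3), rep("eraser", 3), rep("reader", 14))
  )
}
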