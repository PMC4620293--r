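ckr_ligand_table <- list(
  CCR1 = c(CCL3 = "MIP-1a", CCL5 = "RANTES", CCL8 = "MCP-2",
           CCL7 = "MCP-3"),
  CCR2 = c(CCL2 = "MCP-1", CCL8 = "MCP-2", CCL7 = "MCP-3",
           CCL13 = "MCP-4"),
  CCR4 = c(CCL17 = "TARC", CCL22 = "MDC"),
  CCR5 = c(CCL3 = "MIP-1a", CCL4 = "MIP-1b", CCL5 = "RANTES",
           CCL8 = "MCP-2"),
  CCR6 = c(CCL20 = "LARC"),
  CCR7 = c(CCL19 = "ELC", CCL21 = "SLC"),
  CXCR1 = c(CXCL8 = "IL-8"),
  CXCR2 = c(CXCL8 = "IL-8", CXCL1 = "GRO-a"),
  CXCR3 = c(CXCL9 = "MIG", CXCL10 = "IP-10", CXCL11 = "I-TAC"),
  CXCR4 = c(CXCL12 = "SDF-1"))

#' Chemokine receptor to ligand lookup
#'
#' Static reference mapping each chemokine receptor of the NK-cell
#' panels (plus CCR1/CCR2/CCR7, which appear in the cell-partner
#' discussion) to its chemokine ligands. Lookups are case-insensitive;
#' unknown receptors return an empty vector with a warning.
#'
#' @param receptor Receptor name, e.g. `"CXCR3"`.
#' @return Character vector of systematic ligand names (CCL/CXCL), with
#'   common names (MIG, IP-10, ...) as the `names` attribute.
#' @examples
#' ckr_ligands("CXCR3")  # CXCL9, CXCL10, CXCL11
#' ckr_ligands("CXCR4")  # CXCL12
#' @export
ckr_ligands <- function(receptor) {
  hit <- match(toupper(receptor), names(ckr_ligand_table))
  if (is.na(hit)) {
    warning("unknown chemokine receptor '", receptor, "'", call. = FALSE)
    return(character(0))
  }
  lig <- ckr_ligand_table[[hit]]
  stats::setNames(names(lig), unname(lig))
}
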