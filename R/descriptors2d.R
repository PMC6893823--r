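# Topological (2D) descriptors.

#' Compute the topological descriptor block for SMILES input
#'
#' Computes the six 2D members of the descriptor panel: molecular weight,
#' hydrogen-bond donor and acceptor counts, topological polar surface area
#' (Ertl fragment-contribution method), octanol/water logP
#' (Wildman-Crippen atomic-contribution method) and the rotatable-bond
#' count (acyclic single bonds between non-terminal heavy atoms).
#' Deterministic; no 3D information involved.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns smiles, mw, hbd, hba, psa, logp, rotb.
#' @examples
#' compute2D("c1ccccc1")          # benzene: hbd 0, rotb 0
#' @export
compute2D <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  p <- .ob_props(smiles)
  data.frame(
    smiles = smiles,
    mw = p$MW,
    hbd = as.integer(p$HBD),
    hba = as.integer(p$HBA1),
    psa = p$TPSA,
    logp = p$logP,
    rotb = as.integer(.ob_rotb(smiles)),
    stringsAsFactors = FALSE)
}
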