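#' Synthetic stand-in reference lists for the overlap worked example
#'
#' The study's underlying lists — the 63 up-regulated synaptosomal
#' proteins and the 793-protein scaffold (Shank3) interactome — are not
#' publicly deposited. This function builds deterministic SYNTHETIC
#' stand-ins that reproduce the printed summary structure exactly: a
#' 63-member up-regulated list containing six ribosomal proteins and
#' Shank3, and a 793-member interactome sharing exactly eight identifiers
#' (including Shank3) with the up-regulated list, i.e. 8/63 = 12.7%.
#' Real mouse gene symbols are used where natural; interactome filler
#' members use the synthetic prefix `sipx`. These lists validate the
#' overlap machinery and are not the study's data.
#'
#' @return A list with character vectors `upregulated` (length 63) and
#'   `interactome` (length 793), plus `ribosomal` (the six RP symbols)
#'   and `shared` (the eight common identifiers).
#' @examples
#' refs <- synthetic_reference_lists()
#' overlap_stats(refs$upregulated, refs$interactome)
#' @export
synthetic_reference_lists <- function() {
  ribosomal <- c("rplp1", "rpl36a", "rpl22l1", "rps19", "rps2", "mrpl4")
  shared <- c("shank3", "homer1", "dlgap1", "grin2b", "camk2a", "syngap1",
              "dlg4", "ctnnb1")
  up_only <- c(
    "drd1", "ppp1r1b", "gfap", "syt1", "syp", "snap25", "stx1a", "vamp2",
    "syn1", "syn2", "bsn", "pclo", "nrxn1", "nlgn1", "gria1", "gria2",
    "grm5", "gabra1", "gad1", "gad2", "th", "slc6a3", "slc17a7", "calb1",
    "calb2", "pvalb", "penk", "pdyn", "tac1", "adora2a", "drd2", "gpr88",
    "rgs9", "arpp21", "pde10a", "ppp3ca", "prkcb", "camk4", "nefl",
    "nefm", "map2", "tubb3", "actn2", "sptbn1", "ank2", "cacna1b",
    "kcnj4", "scn2a", "atp2b2"
  )
  interactome_named <- c(
    "dlgap2", "dlgap3", "dlgap4", "shank1", "shank2", "grin1", "grin2a",
    "dlg1", "dlg2", "dlg3", "homer2", "homer3", "abi1", "abi2", "cttn",
    "actb", "arpc2", "arpc3", "wasf1", "baiap2", "cyfip1", "cyfip2",
    "nckap1", "fyn", "src", "grb2", "plcb1", "dbnl", "cttnbp2", "lzts3"
  )

  upregulated <- c(ribosomal, shared, up_only)
  filler <- sprintf("sipx%04d", seq_len(793 - length(shared) -
                                          length(interactome_named)))
  interactome <- c(shared, interactome_named, filler)

  stopifnot(
    length(upregulated) == 63,
    length(interactome) == 793,
    !anyDuplicated(upregulated),
    !anyDuplicated(interactome),
    identical(sort(intersect(upregulated, interactome)), sort(shared))
  )
  list(
    upregulated = upregulated,
    interactome = interactome,
    ribosomal = ribosomal,
    shared = shared
  )
}
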