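#' Registry of the study's printed counts, sequences and constants
#'
#' Read-only named fixtures used by the worked examples and the
#' acceptance checks: the CHEF-karyotyped colony counts behind the GCR
#' correction, the tetrad and random-spore viability counts from the
#' dna2-deletion suppression crosses, the three NLS candidate sequences
#' with their full-protein anchors, and the assay constants. Each entry
#' carries a `description` saying what was measured.
#'
#' @return a nested list with components `chef`, `spores`, `sequences`,
#'   `constants`.
#' @examples
#' fx <- assayFixtures()
#' fx$chef$pif1_delta           # 10 rearranged of 23 tested
#' fx$constants$wt_lys_rate     # 3.9e-6 per cell
#' @export
assayFixtures <- function() {
  list(
    chef = list(
      pif1_delta = list(
        n_rearranged = 10L, n_tested = 23L,
        description = "CHEF karyotypes of Ade+ Leu- colonies, pif1 deletion strain"
      ),
      wt = list(
        n_rearranged = 1L, n_tested = 30L,
        description = "CHEF karyotypes of Ade+ Leu- colonies, wild-type PIF1 strain"
      )
    ),
    spores = list(
      tetrad_nlsd = sporeTable(
        ura_plus_g418s = 3L, ura_plus_g418r = 24L,
        ura_minus_g418s = 0L, ura_minus_g418r = 0L,
        source = "tetrad", n_tetrads = 35L
      ),
      tetrad_wt = sporeTable(
        ura_plus_g418s = 0L, ura_plus_g418r = 0L,
        ura_minus_g418s = 0L, ura_minus_g418r = 0L,
        source = "tetrad", n_tetrads = 36L
      ),
      rsa_nlsd = sporeTable(
        ura_plus_g418s = 8L, ura_plus_g418r = 34L,
        ura_minus_g418s = 0L, ura_minus_g418r = 0L,
        source = "rsa"
      ),
      description = paste(
        "Viable spores by Ura/G418 phenotype from DNA2/dna2::URA3",
        "heterozygous crosses; only the Ura+ classes were printed, Ura-",
        "classes are recorded as zero placeholders"
      )
    ),
    sequences = list(
      monopartite_candidate = ProteinSequence(
        "DEQVKKRKLDY", id = "Pif1-monopartite-candidate", anchor = 777L
      ),
      bipartite_candidate = ProteinSequence(
        "RQRGDVKFIDMLNRMRLGNIDDETEREFKKLSRP",
        id = "Pif1-second-candidate", anchor = 417L
      ),
      sv40_nls = ProteinSequence(
        "PKKKRKV", id = "SV40-T-antigen-NLS", anchor = 126L
      )
    ),
    constants = list(
      pif1_length_aa = 859L,
      nls_core = list(start = 781L, end = 784L, matched = "KKRK"),
      synthesis_call_threshold = 1.1,
      droplets_nominal = 20000L,
      locus_offsets_kb = c(P2 = 1.9, P3 = 22.4, P4 = 61.4),
      wt_lys_rate = 3.9e-6,
      pif1_delta_fold_reduction = 27,
      wt_p2_copy_number_10h = 1.7,
      chip_mat_fold_reduction = 4.6
    )
  )
}
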