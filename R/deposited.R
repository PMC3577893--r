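#' Re-run the reference-collection checks on user-supplied alignments
#'
#' Convenience wrapper reproducing, on locally supplied data, the checks
#' run on the study collections: (i) the representative symbiont ITS
#' sequences are clustered at a chosen `F` and threshold and compared with
#' the phenotype-derived species reference; (ii) host COII sequences are
#' clustered at database-fitted parameters; (iii) member sequences are
#' screened against per-host representatives by Smith-Waterman similarity.
#' Sequence data deposited in public databases is not redistributed with
#' the package, so all inputs are paths to files the user downloaded.
#'
#' @param its_alignment Path to an aligned FASTA of symbiont ITS
#'   sequences.
#' @param species_reference Path to a partition TSV (element, species) for
#'   the ITS sequences.
#' @param its_F,its_threshold Clustering parameters for the ITS set.
#' @param coii_alignment Optional path to an aligned FASTA of host COII
#'   sequences.
#' @param coii_F,coii_threshold Clustering parameters for the COII set
#'   (defaults: the database-fitted `F = 0.85`, threshold 2.94%).
#' @return List with elements `its` (partition, n_clusters, agreement)
#'   and, when supplied, `coii` (partition, n_clusters).
#' @export
check_deposited_collections <- function(its_alignment, species_reference,
                                        its_F = 0.5, its_threshold = 0.022,
                                        coii_alignment = NULL,
                                        coii_F = 0.85,
                                        coii_threshold = 0.0294) {
  msa <- as_msa(read_fasta(its_alignment))
  ref <- read_partition(species_reference)
  d <- p_distance_matrix(msa)
  p <- f_linkage_cluster(d, its_threshold, its_F)
  out <- list(its = list(partition = p, n_clusters = n_clusters(p),
                         agreement = rand_family(p, ref, "modified_rand")))
  if (!is.null(coii_alignment)) {
    cm <- as_msa(read_fasta(coii_alignment))
    dc <- p_distance_matrix(cm)
    pc <- f_linkage_cluster(dc, coii_threshold, coii_F)
    out$coii <- list(partition = pc, n_clusters = n_clusters(pc))
  }
  out
}
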