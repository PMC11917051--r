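#' Controlled vocabulary of mitochondrial gene tokens
#'
#' The canonical 40-symbol vocabulary used throughout the package:
#' 13 protein-coding genes, 22 tRNAs (with the two leucine and two serine
#' tRNAs distinguished as \code{trnL1}/\code{trnL2} and
#' \code{trnS1}/\code{trnS2} following the standard anticodon-based
#' designation), 2 rRNAs, the control region (\code{CR}), the light-strand
#' replication origin (\code{OL}), and an open class \code{extra} for
#' features that cannot be mapped.
#'
#' @return Character vector of canonical tokens.
#' @export
mito_vocabulary <- function() {
  c(mito_pcgs(), mito_trnas(), mito_rrnas(), "CR", "OL", "extra")
}

#' @rdname mito_vocabulary
#' @export
mito_pcgs <- function() {
  c("nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6",
    "cox1", "cox2", "cox3", "atp6", "atp8", "cob")
}

#' @rdname mito_vocabulary
#' @export
mito_trnas <- function() {
  c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
    "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
    "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
}

#' @rdname mito_vocabulary
#' @export
mito_rrnas <- function() c("rrnS", "rrnL")

# the 37 genes every intact vertebrate mitogenome is expected to carry
# (CR and OL are not genes; their absence is never an error)
mito_required_genes <- function() c(mito_pcgs(), mito_trnas(), mito_rrnas())

#' Reference gene orders (ground patterns)
#'
#' Built-in circular gene orders used as references and test fixtures:
#' \describe{
#'   \item{\code{vertebrate_order()}}{the typical vertebrate arrangement
#'     (39 labels: 37 genes plus CR and OL), the amphibian ground pattern.}
#'   \item{\code{caudata_order()}}{the Caudata ground pattern: one
#'     additional control region between \code{trnT} and \code{trnP}.}
#'   \item{\code{neobatrachia_order()}}{the Neobatrachian ground pattern:
#'     \code{trnL1} translocated next to \code{trnT}-\code{trnP}, forming
#'     the LTPF tRNA cluster upstream of the 12S rRNA gene.}
#' }
#'
#' @param sample_id sample identifier for the returned order.
#' @param taxon optional (family, genus, species) character vector.
#' @return A canonical [gene_order()].
#' @export
vertebrate_order <- function(sample_id = "vertebrate", taxon = NULL) {
  tokens <- c(
    "trnF", "rrnS", "trnV", "rrnL", "trnL2", "nad1", "trnI", "-trnQ",
    "trnM", "nad2", "trnW", "-trnA", "-trnN", "OL", "-trnC", "-trnY",
    "cox1", "-trnS2", "trnD", "cox2", "trnK", "atp8", "atp6", "cox3",
    "trnG", "nad3", "trnR", "nad4l", "nad4", "trnH", "trnS1", "trnL1",
    "nad5", "-nad6", "-trnE", "cob", "trnT", "-trnP", "CR")
  canonicalize(gene_order(tokens, sample_id = sample_id, taxon = taxon))
}

#' @rdname vertebrate_order
#' @export
caudata_order <- function(sample_id = "caudata", taxon = NULL) {
  v <- format_tokens(vertebrate_order())
  i <- match("trnT", v)
  tokens <- append(v, "CR", after = i)   # extra CR between trnT and trnP
  canonicalize(gene_order(tokens, sample_id = sample_id, taxon = taxon))
}

#' @rdname vertebrate_order
#' @export
neobatrachia_order <- function(sample_id = "neobatrachia", taxon = NULL) {
  v <- format_tokens(vertebrate_order())
  v <- v[v != "trnL1"]                        # leave trnS1 adjacent to nad5
  # move the trnT,-trnP block (with trnL1 prepended) between CR and trnF:
  # linearized from trnF the tail becomes ..., cob, CR, trnL1, trnT, -trnP
  v <- v[!v %in% c("trnT", "-trnP")]
  tokens <- c(v, "trnL1", "trnT", "-trnP")    # v ends with ..., cob, CR
  canonicalize(gene_order(tokens, sample_id = sample_id, taxon = taxon))
}
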