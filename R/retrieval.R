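# Molecular retrieval: rank a corpus by cosine similarity of learned graph
# embeddings to a query, annotated with fingerprint Tanimoto similarity.

#' Path-based structural fingerprint
#'
#' OpenBabel FP2 fingerprint (1024 bits) as a set of on-bit positions.
#'
#' @param smiles A single SMILES string.
#' @return Integer vector of on-bit indices with attribute `nbits`.
#' @export
fingerprint <- function(smiles) {
  bits <- ChemmineOB::fingerprint_OB(
    ChemmineOB::forEachMol("SMILES", smiles, identity), "FP2")
  on <- which(as.numeric(bits) > 0)
  attr(on, "nbits") <- length(bits)
  on
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over on-bit sets. Two empty fingerprints
#' compare as 1 by convention.
#'
#' @param fp_a,fp_b Fingerprints from the same scheme and length (on-bit
#'   index vectors, e.g. from [fingerprint()]).
#' @return Scalar in [0, 1].
#' @export
tanimoto <- function(fp_a, fp_b) {
  na <- attr(fp_a, "nbits"); nb <- attr(fp_b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb)
    stop("fingerprint length mismatch: ", na, " vs ", nb)
  u <- length(union(fp_a, fp_b))
  if (u == 0L) return(1)
  length(intersect(fp_a, fp_b)) / u
}

#' Retrieve the most similar molecules to a query
#'
#' Embeds the query and every corpus molecule with the pre-trained encoder,
#' ranks the corpus by cosine similarity of the graph embeddings to the
#' query (descending, ties broken by corpus index) and annotates each hit
#' with its fingerprint Tanimoto similarity to the query.
#'
#' @param query A SMILES string or `molgraph`.
#' @param corpus Character vector of SMILES or list of `molgraph`.
#' @param object A fitted `molemcl` model (or checkpoint path).
#' @param k Number of hits to return (at most the corpus size).
#' @return A data.frame with columns `rank`, `index`, `smiles`, `cosine`,
#'   `tanimoto`.
#' @export
retrieve_similar <- function(query, corpus, object, k = 4L) {
  if (is.character(object)) object <- load_checkpoint(object)
  stopifnot(inherits(object, "molemcl"))
  if (is.character(corpus)) corpus <- smiles_to_graph_batch(corpus,
                                                            vocab = object$vocab)
  if (is.character(query)) query <- smiles_to_graph(query, object$vocab)
  if (k > length(corpus)) stop("k exceeds the corpus size (", length(corpus), ")")
  emb <- predict(object, corpus)
  qv <- as.numeric(predict(object, list(query)))
  cos <- apply(emb, 1L, cosine_similarity, b = qv)
  ord <- order(-cos, seq_along(cos))[seq_len(k)]
  qfp <- fingerprint(query$smiles)
  data.frame(
    rank = seq_len(k), index = ord,
    smiles = vapply(corpus[ord], `[[`, character(1), "smiles"),
    cosine = cos[ord],
    tanimoto = vapply(corpus[ord],
                      function(g) tanimoto(qfp, fingerprint(g$smiles)),
                      numeric(1)),
    row.names = NULL)
}
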