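# Packaged controlled vocabulary: every emitted annotation track is keyed
# by one term from each of the three namespaces (evidence, feature, source).

.cv <- local({
  ev <- function(name, def) data.frame(namespace = "evidence", name = name,
                                       definition = def, stringsAsFactors = FALSE)
  fe <- function(name, def) data.frame(namespace = "feature", name = name,
                                       definition = def, stringsAsFactors = FALSE)
  so <- function(name, def) data.frame(namespace = "source", name = name,
                                       definition = def, stringsAsFactors = FALSE)
  rbind(
    ev("curated", "manually curated annotation from a member database"),
    ev("derived", "annotation derived from experimental structures"),
    ev("homology", "annotation transferred from a homologous protein"),
    ev("prediction", "annotation predicted by software"),
    fe("disorder", "intrinsically disordered region"),
    fe("lip", "linear interacting peptide (binding IDR in extended conformation)"),
    fe("llps", "region driving liquid-liquid phase separation"),
    fe("binding_mode", "conformational transition class of a binding IDR"),
    fe("conservation", "sequence-logo conservation track"),
    so("alphafold-plddt", "low per-residue confidence in a predicted structure"),
    so("alphafold-rsa", "window-averaged relative solvent accessibility of a predicted structure"),
    so("alphafold", "intersection of confident and exposed residues in a predicted structure"),
    so("logo", "consensus-character height from a query-anchored alignment logo"),
    so("disprot", "curated disorder/LIP member database"),
    so("ideal", "curated disorder/LIP member database"),
    so("elm", "curated short linear motif database"),
    so("dibs", "curated database of LIPs bound to ordered partners"),
    so("mfib", "curated database of mutual folding induced by binding"),
    so("fuzdb", "curated database of fuzzy complexes"),
    so("codnas", "curated database of conformational diversity"),
    so("phasepro", "curated LLPS region database"),
    so("phasepdb", "curated LLPS region database"),
    so("uniprot", "curated regions from UniProtKB feature lines")
  )
})

#' The packaged controlled vocabulary
#'
#' @param namespace Optional filter: `"evidence"`, `"feature"` or
#'   `"source"`.
#' @return `data.frame` with columns `namespace`, `name`, `definition`.
#' @export
cv_terms <- function(namespace = NULL) {
  if (is.null(namespace)) return(.cv)
  namespace <- match.arg(namespace, c("evidence", "feature", "source"))
  .cv[.cv$namespace == namespace, , drop = FALSE]
}

#' Check that a CV triplet is known
#'
#' @param evidence,feature,source Term names, one per namespace.
#' @return TRUE invisibly; unknown terms raise an error.
#' @export
cv_validate_triplet <- function(evidence, feature, source) {
  chk <- function(ns, term) {
    ok <- term %in% .cv$name[.cv$namespace == ns]
    if (!ok) stop(sprintf("unknown %s term '%s'", ns, term), call. = FALSE)
  }
  chk("evidence", evidence); chk("feature", feature); chk("source", source)
  invisible(TRUE)
}
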