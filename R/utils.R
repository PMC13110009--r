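#' @importFrom rlang %||% .data
NULL

#' dcims: Dimensional Cophenetic Integrity for MSI embeddings
#'
#' Tools to score and optimize the preservation of hierarchical cluster
#' relationships when mass spectrometry imaging datacubes are reduced to
#' low-dimensional embeddings. See [dci()] for the score itself,
#' [synthesize_cube()] for the synthetic MALDI generator, and
#' [bayes_optimize()] for DCI-guided hyperparameter optimization.
#'
#' @keywords internal
"_PACKAGE"
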