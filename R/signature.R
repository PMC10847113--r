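#' Gene signature with up- and down-regulated sets
#'
#' A named pair of disjoint gene sets. The up set collects genes
#' over-expressed in the highly connected (or otherwise "high") condition,
#' the down set genes over-expressed in the opposite condition.
#'
#' @param name signature name
#' @param up,down character vectors of gene ids (duplicates removed,
#'   order preserved); the two sets must be disjoint
#' @param provenance free-form record of how the signature was derived
#' @return an object of class `gene_signature`
#' @export
gene_signature <- function(name, up = character(), down = character(),
                           provenance = NULL) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down))) {
    stop("up and down gene sets must be disjoint")
  }
  structure(list(name = name, up = up, down = down, provenance = provenance),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes (%d up / %d down)\n",
              x$name, length(x$up) + length(x$down),
              length(x$up), length(x$down)))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) length(x$up) + length(x$down)

#' Remove control-signature genes from a signature
#'
#' Drops from `sig` every gene that appears in `ctrl` (in either direction).
#' Used to correct a calcium-activity signature for calcium-independent
#' labeling (dye diffusion): genes shared with the constitutively labeling
#' control signature are excluded.
#'
#' @param sig the signature to correct
#' @param ctrl the control signature whose genes are removed
#' @return a `gene_signature` named `<sig$name>_corrected`
#' @export
diffusion_correct <- function(sig, ctrl) {
  stopifnot(inherits(sig, "gene_signature"), inherits(ctrl, "gene_signature"))
  remove <- union(ctrl$up, ctrl$down)
  gene_signature(
    paste0(sig$name, "_corrected"),
    up = setdiff(sig$up, remove),
    down = setdiff(sig$down, remove),
    provenance = list(source = sig$name, control = ctrl$name)
  )
}

#' Overlap between two gene signatures
#'
#' @param a,b `gene_signature` objects
#' @return list with the shared gene ids (`genes`), their number (`n`), and
#'   the sizes of both signatures
#' @export
signature_overlap <- function(a, b) {
  ga <- union(a$up, a$down)
  gb <- union(b$up, b$down)
  shared <- intersect(ga, gb)
  list(genes = shared, n = length(shared),
       n_a = length(ga), n_b = length(gb))
}
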