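#' Construct a Boolean gene regulatory network
#'
#' A gene regulatory network (GRN) is specified by an integer interaction
#' matrix `W` and an integer threshold vector `theta`.  Entry `W[i, j]` is the
#' signed influence of gene `j` on gene `i` (positive = activation, negative =
#' repression, zero = no edge).  The synchronous Boolean dynamics are
#' `x_i(t+1) = H(sum_j W[i,j] x_j(t) - theta_i)` with `H` the Heaviside step
#' function, `H(x) = 1` for `x > 0` and `0` otherwise, so ties never activate.
#'
#' @param genes character vector of unique gene names.
#' @param W square numeric matrix of integer interaction weights; row `i`
#'   collects the regulators of gene `i`.
#' @param theta numeric vector of integer activation thresholds, one per gene.
#' @return An object of class `gene_network` with elements `genes`, `W`,
#'   `theta`.
#' @seealso [boolean_step()], [boolean_fixed_points()], [at_flower_network()],
#'   [toy_network()]
#' @examples
#' net <- toy_network("toggle")
#' boolean_fixed_points(net)
#' @export
gene_network <- function(genes, W, theta) {
  genes <- as.character(genes)
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  theta <- as.numeric(theta)
  n <- length(genes)
  if (n < 1L) stop_("a network needs at least one gene")
  if (anyDuplicated(genes)) stop_("gene names must be unique")
  if (nrow(W) != ncol(W)) stop_("'W' must be square")
  if (nrow(W) != n || length(theta) != n)
    stop_(sprintf(
      "dimension mismatch: %d genes, W is %dx%d, theta has length %d",
      n, nrow(W), ncol(W), length(theta)))
  if (any(!is.finite(W)) || any(!is.finite(theta)))
    stop_("'W' and 'theta' must be finite")
  dimnames(W) <- list(genes, genes)
  names(theta) <- genes
  structure(list(genes = genes, W = W, theta = theta),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  n <- length(x$genes)
  cat(sprintf("Boolean gene regulatory network: %d genes, %d interactions\n",
              n, sum(x$W != 0)))
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' One synchronous Boolean update
#'
#' Applies the threshold rule `x_i' = H(sum_j W[i,j] x_j - theta_i)` to every
#' gene simultaneously.  `H(0) = 0`: a gene whose input exactly meets its
#' threshold stays (or becomes) inactive.
#'
#' @param state binary vector (0/1), one entry per gene.
#' @param net a [gene_network()].
#' @return The successor binary state vector.
#' @export
boolean_step <- function(state, net) {
  stopifnot(inherits(net, "gene_network"))
  state <- as.numeric(state)
  n <- length(net$genes)
  if (length(state) != n)
    stop_(sprintf("state length %d does not match network size %d",
                  length(state), n))
  if (!all(state %in% c(0, 1))) stop_("state entries must be 0 or 1")
  as.numeric(drop(net$W %*% state) - net$theta > 0)
}

#' Enumerate the fixed points of the synchronous Boolean dynamics
#'
#' Exhaustively checks all `2^N` states and returns those invariant under
#' [boolean_step()], in lexicographic order (first gene most significant).
#' These fixed points are the Boolean attractors that the continuous model's
#' point attractors and the mixture components of the fitted stationary
#' density are expected to shadow.
#'
#' @param net a [gene_network()] with at most `max_genes` genes.
#' @param max_genes guard on the exhaustive enumeration (default 24).
#' @return A matrix with one fixed point per row, columns named by gene.
#' @export
boolean_fixed_points <- function(net, max_genes = 24L) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$genes)
  if (n > max_genes)
    stop_(sprintf(paste0(
      "network has %d genes; exhaustive enumeration supports at most %d. ",
      "Use a sampling-based search instead (not provided)."), n, max_genes))
  # All states as rows of a 2^n x n binary matrix, lexicographic order.
  states <- as.matrix(expand.grid(rev(replicate(n, c(0, 1), simplify = FALSE)),
                                  KEEP.OUT.ATTRS = FALSE))[, n:1, drop = FALSE]
  colnames(states) <- net$genes
  inputs <- states %*% t(net$W)
  nxt <- (inputs - rep(net$theta, each = nrow(states))) > 0
  fixed <- rowSums(nxt != (states == 1)) == 0L
  out <- states[fixed, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write a network as JSON
#'
#' The file format is a JSON object `{"genes": [...], "W": [[...]],
#' "theta": [...]}` with `W` row `i` holding the regulators of target gene `i`.
#'
#' @param path file path.
#' @return `read_network_json` returns a [gene_network()];
#'   `write_network_json` returns `path` invisibly.
#' @export
read_network_json <- function(path) {
  if (!file.exists(path)) stop_(sprintf("network file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$genes) || is.null(obj$W) || is.null(obj$theta))
    stop_("network JSON must have fields 'genes', 'W', 'theta'")
  gene_network(obj$genes, obj$W, obj$theta)
}

#' @rdname read_network_json
#' @param net a [gene_network()].
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  obj <- list(genes = net$genes, W = unname(net$W),
              theta = unname(net$theta))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' The Arabidopsis thaliana flower-morphogenesis network
#'
#' The packaged 12-gene GRN underlying A. thaliana flower morphogenesis
#' (genes EMF1, TFL1, LFY, AP1, CAL, LUG, UFO, BFU, AG, AP3, PI, SUP), with
#' integer weights and thresholds whose synchronous Boolean dynamics have at
#' least four fixed points, matching the four floral phenotypic stages.
#'
#' @return A [gene_network()] of 12 genes.
#' @export
at_flower_network <- function() {
  read_network_json(system.file("extdata", "at_flower_network.json",
                                package = "grnlandscape", mustWork = TRUE))
}

#' Small synthetic networks for testing and illustration
#'
#' * `single_gene`: one unregulated gene (continuous model
#'   `dp/dt = alpha0 - delta p`).
#' * `toggle`: two mutually repressing genes with negative thresholds
#'   (`W = [[0,-1],[-1,0]]`, `theta = (-1,-1)`); its Boolean dynamics have
#'   exactly the two antisymmetric fixed points.
#' * `chain3`: an activation cascade 1 -> 2 -> 3.
#'
#' @param kind one of `"single_gene"`, `"toggle"`, `"chain3"`.
#' @return A [gene_network()].
#' @export
toy_network <- function(kind = c("single_gene", "toggle", "chain3")) {
  kind <- match.arg(kind)
  switch(kind,
    single_gene = gene_network("g1", matrix(0, 1, 1), 0),
    toggle = gene_network(c("g1", "g2"),
                          matrix(c(0, -1, -1, 0), 2, 2, byrow = TRUE),
                          c(-1, -1)),
    chain3 = gene_network(c("g1", "g2", "g3"),
                          matrix(c(0, 0, 0,
                                   1, 0, 0,
                                   0, 1, 0), 3, 3, byrow = TRUE),
                          c(-1, 0, 0))
  )
}
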