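#' Gold-standard network
#'
#' Reference edge set used for sensitivity/specificity scoring. Edges are
#' ordered pairs (regulator j -> target i); self-edges are allowed and
#' scored. Signs (+1 induction, -1 repression) are carried along but not used
#' by presence/absence scoring.
#'
#' @param edges data frame with columns `regulator`, `target` (gene names or
#'   1-based indices) and optionally `sign`.
#' @param gene_names character vector defining the gene panel and its order.
#' @return An object of class `gold_standard` with an n x n 0/1 `adjacency`
#'   matrix (rows = targets, columns = regulators) and a `sign` matrix.
#' @export
gold_standard <- function(edges, gene_names) {
  n <- length(gene_names)
  reg <- match_gene(edges$regulator, gene_names)
  tgt <- match_gene(edges$target, gene_names)
  if (anyDuplicated(cbind(reg, tgt)))
    stop("duplicate edges in gold standard")
  adj <- matrix(0L, n, n, dimnames = list(gene_names, gene_names))
  sgn <- matrix(0, n, n, dimnames = list(gene_names, gene_names))
  adj[cbind(tgt, reg)] <- 1L
  sgn[cbind(tgt, reg)] <- if (!is.null(edges$sign)) edges$sign else 0
  structure(list(adjacency = adj, sign = sgn, gene_names = gene_names),
            class = "gold_standard")
}

match_gene <- function(x, gene_names) {
  if (is.numeric(x)) {
    idx <- as.integer(x)
  } else {
    idx <- match(as.character(x), gene_names)
  }
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(gene_names)))
    stop("unknown gene in edge list")
  idx
}

#' @export
print.gold_standard <- function(x, ...) {
  cat(sprintf("gold_standard: %d genes, %d edges\n",
              length(x$gene_names), sum(x$adjacency)))
  invisible(x)
}

#' Threshold a summary weight matrix into a discrete network
#'
#' Entries with |weight| below `magnitude_threshold` are pruned to zero
#' (no edge); surviving entries keep their value, whose sign encodes
#' induction (+) or repression (-). Row i, column j is the influence of
#' regulator j on target i.
#'
#' @param W n x n summary weight matrix (see [static_weight_matrix()]).
#' @param magnitude_threshold non-negative pruning threshold (default 0.5).
#' @return An object of class `network_prediction` with fields `weights` and
#'   `gene_names`.
#' @export
extract_network <- function(W, magnitude_threshold = 0.5) {
  W <- as.matrix(W)
  if (magnitude_threshold < 0) stop("threshold must be non-negative")
  if (any(!is.finite(W))) stop("weights must be finite")
  gene_names <- rownames(W)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(nrow(W)))
  W[abs(W) < magnitude_threshold] <- 0
  dimnames(W) <- list(gene_names, gene_names)
  structure(list(weights = W, gene_names = gene_names),
            class = "network_prediction")
}

#' @export
print.network_prediction <- function(x, ...) {
  cat(sprintf("network_prediction: %d genes, %d edges\n",
              length(x$gene_names), sum(x$weights != 0)))
  invisible(x)
}

#' Z-score consensus across independent runs
#'
#' Stochastic optimisation predicts somewhat different regulations run to
#' run. For each ordered gene pair this computes the mean and standard
#' deviation of its summary weight over R runs and keeps the pair only when
#' its consistency score |Z| = |mean/sd| reaches `Z_th` *and* the mean
#' magnitude reaches `magnitude_threshold`. A pair with zero spread is kept
#' when its mean is nonzero (perfect consistency) and dropped when the mean
#' is zero.
#'
#' @param run_matrices list of R (>= 2) n x n summary weight matrices.
#' @param Z_th Z-score threshold (default 1.0).
#' @param magnitude_threshold minimum |mean| for a retained edge.
#' @return An object of class `consensus_result` with `mean`, `sd`, `Z`,
#'   `retained` (0/1 matrix) and the consensus [extract_network()]-style
#'   `network` whose weights are the retained means.
#' @export
zscore_consensus <- function(run_matrices, Z_th = 1.0,
                             magnitude_threshold = 0.5) {
  R <- length(run_matrices)
  if (R < 2L) stop("consensus needs at least 2 runs")
  dims <- dim(run_matrices[[1]])
  arr <- array(unlist(run_matrices), dim = c(dims, R))
  mu <- apply(arr, c(1, 2), mean)
  sd_ <- apply(arr, c(1, 2), stats::sd)
  Z <- ifelse(sd_ > 0, mu / sd_, ifelse(mu != 0, Inf, 0))
  retained <- (abs(Z) >= Z_th) & (abs(mu) >= magnitude_threshold)
  gene_names <- rownames(run_matrices[[1]])
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(dims[1]))
  W <- ifelse(retained, mu, 0)
  dimnames(W) <- dimnames(mu) <- dimnames(sd_) <- dimnames(Z) <-
    list(gene_names, gene_names)
  structure(list(mean = mu, sd = sd_, Z = Z,
                 retained = retained * 1L,
                 network = structure(list(weights = W,
                                          gene_names = gene_names),
                                     class = "network_prediction")),
            class = "consensus_result")
}

#' Gold standard implied by S-system kinetic orders
#'
#' Component j regulates component i whenever it appears in gene i's
#' production or degradation term, i.e. g_ij != 0 or h_ij != 0 (so the
#' universal self-degradation h_ii != 0 yields a self-edge). For the
#' five-gene benchmark this gives 12 edges.
#'
#' @param p an [ssystem_params()] object.
#' @return a [gold_standard()].
#' @export
gold_from_ssystem <- function(p) {
  stopifnot(inherits(p, "ssystem_params"))
  adj <- (p$g != 0 | p$h != 0) * 1L
  idx <- which(adj == 1L, arr.ind = TRUE)
  # signs are left unset: a pair may appear with mixed signs in g and h,
  # so no unique activation/repression label exists
  gold_standard(
    data.frame(regulator = as.integer(idx[, 2]),
               target = as.integer(idx[, 1]),
               sign = rep(0, nrow(idx))),
    gene_names = p$gene_names
  )
}

#' Sensitivity and specificity of a predicted network
#'
#' Presence/absence comparison over all n^2 ordered gene pairs (self-pairs
#' included): Sn = TP/(TP+FN), Sp = TN/(TN+FP). Edge signs are compared
#' separately (`sign_agreement`: fraction of true positives whose predicted
#' sign matches a nonzero gold sign) and do not enter Sn/Sp.
#'
#' @param pred a [network_prediction()] (or bare weight matrix).
#' @param gold a [gold_standard()].
#' @return list with `Sn`, `Sp`, `TP`, `FP`, `TN`, `FN`, `sign_agreement`.
#' @export
sensitivity_specificity <- function(pred, gold) {
  W <- if (inherits(pred, "network_prediction")) pred$weights
       else as.matrix(pred)
  stopifnot(inherits(gold, "gold_standard"))
  if (!all(dim(W) == dim(gold$adjacency)))
    stop("prediction and gold standard dimensions differ")
  predicted <- W != 0
  actual <- gold$adjacency == 1L
  TP <- sum(predicted & actual)
  FP <- sum(predicted & !actual)
  FN <- sum(!predicted & actual)
  TN <- sum(!predicted & !actual)
  tp_signed <- predicted & actual & gold$sign != 0
  sign_agreement <- if (sum(tp_signed) > 0)
    sum(sign(W[tp_signed]) == gold$sign[tp_signed]) / sum(tp_signed)
  else NA_real_
  list(Sn = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       Sp = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       TP = TP, FP = FP, TN = TN, FN = FN,
       sign_agreement = sign_agreement)
}
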