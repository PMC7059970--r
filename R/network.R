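#' Network specification
#'
#' Population sizes and connection probabilities for the striatal microcircuit.
#' FSI pairs form dendro-dendritic gap junctions with probability `p_fsi_gj`
#' and somato-somatic inhibitory synapses with probability `p_fsi_inh`; each
#' FSI contacts each SPN with probability `p_fsi_spn`; SPNs inhibit all other
#' SPNs of the same receptor subtype (`p_spn_spn = 1`), with no D1-D2 cross
#' connections and no SPN-to-FSI feedback.
#'
#' @param n_fsi,n_d1,n_d2 Population sizes.
#' @param p_fsi_gj,p_fsi_inh,p_fsi_spn,p_spn_spn Connection probabilities.
#' @param seed RNG seed used by [build_connectivity()].
#' @param pairwise_fsi_inh If `TRUE` (default) a single draw per unordered FSI
#'   pair creates a reciprocal inhibitory synapse pair; if `FALSE` each
#'   directed edge is drawn independently.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_fsi = 50, n_d1 = 100, n_d2 = 100,
                         p_fsi_gj = 0.33, p_fsi_inh = 0.58,
                         p_fsi_spn = 0.375, p_spn_spn = 1.0,
                         seed = 1L, pairwise_fsi_inh = TRUE) {
  pr <- c(p_fsi_gj, p_fsi_inh, p_fsi_spn, p_spn_spn)
  if (any(pr < 0 | pr > 1)) stop("connection probabilities must lie in [0,1]", call. = FALSE)
  if (n_fsi < 1 || n_d1 < 1 || n_d2 < 1) stop("population sizes must be >= 1", call. = FALSE)
  structure(list(n_fsi = as.integer(n_fsi), n_d1 = as.integer(n_d1),
                 n_d2 = as.integer(n_d2),
                 p_fsi_gj = p_fsi_gj, p_fsi_inh = p_fsi_inh,
                 p_fsi_spn = p_fsi_spn, p_spn_spn = p_spn_spn,
                 seed = as.integer(seed), pairwise_fsi_inh = pairwise_fsi_inh),
            class = c("network_spec", "striatr_params"))
}

#' Realise random connectivity
#'
#' Draws the adjacency matrices for a [network_spec()], reproducibly from its
#' seed. Gap junctions are symmetric with zero diagonal (one Bernoulli draw
#' per unordered pair); FSI-FSI inhibition is reciprocal-per-pair by default;
#' FSI->SPN edges are independent Bernoulli draws per (FSI, SPN) pair for each
#' subpopulation; SPN-SPN adjacency is all-to-all within subpopulation
#' (excluding autapses) scaled by `p_spn_spn` draws when `p_spn_spn < 1`.
#'
#' @param spec A [network_spec()].
#' @return An object of class `connectivity` with elements `gj` (n_fsi x
#'   n_fsi), `fsi_inh` (n_fsi x n_fsi, row = presynaptic), `fsi_d1`, `fsi_d2`
#'   (n_fsi x n_d*), `d1_d1`, `d2_d2` (within-subpopulation), and the spec.
#' @examples
#' cm <- build_connectivity(network_spec(n_fsi = 4, n_d1 = 5, n_d2 = 5))
#' isSymmetric(cm$gj)
#' @export
build_connectivity <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  nf <- spec$n_fsi
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    code
  }
  res <- withr_seed({
    gj <- matrix(0L, nf, nf)
    inh <- matrix(0L, nf, nf)
    if (nf > 1) {
      for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
        if (stats::runif(1) < spec$p_fsi_gj) gj[i, j] <- gj[j, i] <- 1L
        if (spec$pairwise_fsi_inh) {
          if (stats::runif(1) < spec$p_fsi_inh) inh[i, j] <- inh[j, i] <- 1L
        } else {
          if (stats::runif(1) < spec$p_fsi_inh) inh[i, j] <- 1L
          if (stats::runif(1) < spec$p_fsi_inh) inh[j, i] <- 1L
        }
      }
    }
    fsi_d1 <- matrix(as.integer(stats::runif(nf * spec$n_d1) < spec$p_fsi_spn),
                     nf, spec$n_d1)
    fsi_d2 <- matrix(as.integer(stats::runif(nf * spec$n_d2) < spec$p_fsi_spn),
                     nf, spec$n_d2)
    all_to_all <- function(n, p) {
      m <- if (p >= 1) matrix(1L, n, n)
           else matrix(as.integer(stats::runif(n * n) < p), n, n)
      diag(m) <- 0L
      m
    }
    list(gj = gj, fsi_inh = inh, fsi_d1 = fsi_d1, fsi_d2 = fsi_d2,
         d1_d1 = all_to_all(spec$n_d1, spec$p_spn_spn),
         d2_d2 = all_to_all(spec$n_d2, spec$p_spn_spn))
  })
  structure(c(res, list(spec = spec)), class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat("<connectivity>", x$spec$n_fsi, "FSI,", x$spec$n_d1, "D1,",
      x$spec$n_d2, "D2\n")
  cat("  gap junctions:", sum(x$gj) / 2, " FSI-FSI inhibitory:", sum(x$fsi_inh),
      "\n  FSI->D1:", sum(x$fsi_d1), " FSI->D2:", sum(x$fsi_d2), "\n")
  invisible(x)
}

#' GABA-A gate dynamics
#'
#' Kinetics of a single synaptic gate driven by the presynaptic voltage:
#' `dS/dt = g_open(V_pre) (1 - S) - S / tau_i`. SPN-sourced synapses open at
#' rate `2 (1 + tanh(V/4))`; FSI-sourced synapses open at
#' `(1/tau_r)(1 + tanh(V/10))`.
#'
#' @param S Gate value in \[0,1\]; vectorised with `V_pre`.
#' @param V_pre Presynaptic (somatic) voltage (mV).
#' @param kind `"spn-source"` or `"fsi-source"`.
#' @param params A [synapse_params()] object.
#' @return dS/dt (1/ms).
#' @export
gaba_gate_rhs <- function(S, V_pre, kind = c("spn-source", "fsi-source"),
                          params = synapse_params()) {
  kind <- match.arg(kind)
  if (any(S < 0 | S > 1)) stop("S must lie in [0,1]", call. = FALSE)
  g_open <- gaba_open_rate(V_pre, kind, params)
  g_open * (1 - S) - S / params$tau_i
}

gaba_open_rate <- function(V_pre, kind, params = synapse_params()) {
  switch(kind,
    "spn-source" = 2 * (1 + tanh(V_pre / 4)),
    "fsi-source" = (1 / params$tau_r) * (1 + tanh(V_pre / 10)),
    stop("unknown synapse kind: ", kind, call. = FALSE))
}

#' Postsynaptic GABA-A current
#'
#' `I_j = g (sum_k A[k,j] S_k) (V_j - E_i)` for each postsynaptic cell j,
#' outward positive.
#'
#' @param S Per-presynaptic-cell gate values (length = nrow(adjacency)).
#' @param adjacency 0/1 matrix, rows presynaptic, columns postsynaptic.
#' @param g Per-connection maximal conductance (mS/cm^2).
#' @param V_post Postsynaptic voltages (length = ncol(adjacency)).
#' @param E_i Reversal potential (mV).
#' @return Current per postsynaptic cell (uA/cm^2).
#' @export
synaptic_current <- function(S, adjacency, g, V_post, E_i = -80) {
  if (length(S) != nrow(adjacency) || length(V_post) != ncol(adjacency)) {
    stop("shape mismatch between S, adjacency and V_post", call. = FALSE)
  }
  drop(g * crossprod(adjacency, S)) * (V_post - E_i)
}

#' Gap-junction currents
#'
#' `I_i = g_gj sum_j A[i,j] (V_dj - V_di)`, inward positive; summed over the
#' whole network these currents cancel exactly.
#'
#' @param V_dend Per-FSI dendritic voltages (mV).
#' @param gj_adj Symmetric 0/1 adjacency with zero diagonal.
#' @param g_gj Gap-junction conductance (mS/cm^2).
#' @return Current per FSI dendrite (uA/cm^2).
#' @export
gap_junction_currents <- function(V_dend, gj_adj, g_gj) {
  if (!isSymmetric(unname(gj_adj))) stop("gap-junction adjacency must be symmetric", call. = FALSE)
  deg <- rowSums(gj_adj)
  g_gj * (drop(gj_adj %*% V_dend) - deg * V_dend)
}

#' Export / import connectivity as an edge list
#'
#' Writes a tab-separated edge list (`pre_id`, `post_id`, `type`,
#' `conductance`) covering gap junctions and all GABA-A connection classes,
#' and reads it back into a `connectivity` object for exact re-runs. Cell ids
#' are 1-based within class-specific index spaces (FSI, D1, D2).
#'
#' @param conn A `connectivity` object.
#' @param path File path.
#' @param syn A [synapse_params()] (conductances recorded per edge).
#' @param g_gj Gap-junction conductance recorded for `gap` edges.
#' @return `read_edges()` returns a `connectivity`; `write_edges()` the path,
#'   invisibly.
#' @export
write_edges <- function(conn, path, syn = synapse_params(), g_gj = syn$g_gj) {
  stopifnot(inherits(conn, "connectivity"))
  mat_edges <- function(m, type, g) {
    idx <- which(m != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(pre_id = idx[, 1], post_id = idx[, 2], type = type, conductance = g)
  }
  ed <- rbind(
    mat_edges(conn$gj, "gap", g_gj),
    mat_edges(conn$fsi_inh, "fsi_fsi", syn$g_fsi_fsi),
    mat_edges(conn$fsi_d1, "fsi_d1", syn$g_fsi_spn),
    mat_edges(conn$fsi_d2, "fsi_d2", syn$g_fsi_spn),
    mat_edges(conn$d1_d1, "d1_d1", syn$g_spn_spn),
    mat_edges(conn$d2_d2, "d2_d2", syn$g_spn_spn)
  )
  hdr <- sprintf("# n_fsi=%d n_d1=%d n_d2=%d", conn$spec$n_fsi, conn$spec$n_d1,
                 conn$spec$n_d2)
  writeLines(c(hdr, paste(c("pre_id", "post_id", "type", "conductance"),
                          collapse = "\t")), path)
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  hdr <- readLines(path, n = 1)
  sizes <- as.integer(sub(".*n_fsi=(\\d+) n_d1=(\\d+) n_d2=(\\d+).*", "\\1 \\2 \\3", hdr) |>
                        strsplit(" ") |> unlist())
  ed <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  nf <- sizes[1]; n1 <- sizes[2]; n2 <- sizes[3]
  fill <- function(type, nr, nc) {
    m <- matrix(0L, nr, nc)
    sel <- ed$type == type
    m[cbind(ed$pre_id[sel], ed$post_id[sel])] <- 1L
    m
  }
  structure(list(gj = fill("gap", nf, nf), fsi_inh = fill("fsi_fsi", nf, nf),
                 fsi_d1 = fill("fsi_d1", nf, n1), fsi_d2 = fill("fsi_d2", nf, n2),
                 d1_d1 = fill("d1_d1", n1, n1), d2_d2 = fill("d2_d2", n2, n2),
                 spec = network_spec(n_fsi = nf, n_d1 = n1, n_d2 = n2)),
            class = "connectivity")
}
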