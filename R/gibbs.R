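# Kullback-Leibler information of one cluster's count matrix (20 x 9,
# residues in rows) against the background, in bits:
#   sum_{p,a} count[a,p] * log2(phat[a,p] / bg[a]),
# with phat = (count + pc * bg) / (n + pc). Empty clusters contribute 0.
cluster_kld <- function(counts, n, bg, pseudocount) {
  if (n == 0) return(0)
  phat <- (counts + pseudocount * bg) / (n + pseudocount)
  sum(counts * log2(phat / bg))
}

#' Gibbs-sampling motif deconvolution of 9-mer peptides
#'
#' Partitions fixed-length 9-mers into `g` motif clusters by annealed Gibbs
#' sampling. The objective is the total Kullback-Leibler information of the
#' cluster position-specific residue distributions against the background.
#' Each sweep proposes a new cluster for every peptide in turn, sampling
#' among clusters with probability proportional to `exp(objective / T)`; the
#' temperature is annealed geometrically from `t_start` to `t_end`. The
#' best-objective state per `g` is retained and the selected cluster number
#' is the `g` with the highest final objective. This is a simplified
#' re-implementation of motif deconvolution: fixed length 9, no trash
#' cluster, no sequence weighting.
#'
#' @param peptides Character vector of 9-mers (at least `20 * max(g_range)`).
#' @param g_range Cluster numbers to try (default 1:6).
#' @param iterations Sweeps over all peptides per `g` (default 50).
#' @param t_start,t_end Annealing temperatures.
#' @param seed Integer seed; runs are reproducible.
#' @param background_freqs Residue background (default uniform).
#' @param pseudocount Pseudocount for cluster PSSMs.
#' @return A `gibbs_result`: list with `runs` (tibble `g`, `kld`), `states`
#'   (per `g`: `assignments`, `pssms`, `kld`), and `selected_g`.
#' @export
gibbs_cluster <- function(peptides, g_range = 1:6, iterations = 50,
                          t_start = 1.5, t_end = 0.05, seed = 1,
                          background_freqs = NULL, pseudocount = 1) {
  if (any(nchar(peptides) != 9)) {
    stop("gibbs_cluster is a fixed-length implementation: all peptides must ",
         "be 9-mers", call. = FALSE)
  }
  n <- length(peptides)
  if (n < 20 * max(g_range)) {
    stop("need at least 20 * max(g_range) peptides", call. = FALSE)
  }
  bg <- aa_background(background_freqs)
  idx <- peptide_index_matrix(peptides)
  pos <- seq_len(9)

  run_one <- function(g) {
    set.seed(seed + g)
    assign <- sample.int(g, n, replace = TRUE)
    counts <- lapply(seq_len(g), function(c) {
      m <- matrix(0, 20, 9)
      for (j in pos) {
        t <- tabulate(idx[assign == c, j], 20)
        m[, j] <- t
      }
      m
    })
    size <- tabulate(assign, g)
    obj <- vapply(seq_len(g), function(c) {
      cluster_kld(counts[[c]], size[c], bg, pseudocount)
    }, numeric(1))
    temps <- t_start * (t_end / t_start)^(seq_len(iterations) / iterations)
    best <- list(kld = sum(obj), assign = assign)
    for (it in seq_len(iterations)) {
      temp <- temps[it]
      for (i in seq_len(n)) {
        c0 <- assign[i]
        cells <- cbind(idx[i, ], pos)
        counts[[c0]][cells] <- counts[[c0]][cells] - 1
        size[c0] <- size[c0] - 1L
        obj[c0] <- cluster_kld(counts[[c0]], size[c0], bg, pseudocount)
        base <- sum(obj)
        vals <- numeric(g)
        for (c in seq_len(g)) {
          m <- counts[[c]]
          m[cells] <- m[cells] + 1
          vals[c] <- base - obj[c] + cluster_kld(m, size[c] + 1L, bg,
                                                 pseudocount)
        }
        pr <- exp((vals - max(vals)) / temp)
        cnew <- if (g == 1) 1L else sample.int(g, 1, prob = pr)
        counts[[cnew]][cells] <- counts[[cnew]][cells] + 1
        size[cnew] <- size[cnew] + 1L
        obj[cnew] <- cluster_kld(counts[[cnew]], size[cnew], bg, pseudocount)
        assign[i] <- cnew
        tot <- sum(obj)
        if (tot > best$kld) best <- list(kld = tot, assign = assign)
      }
    }
    pssms <- lapply(seq_len(g), function(c) {
      m <- matrix(0, 20, 9, dimnames = list(AA20, NULL))
      for (j in pos) m[, j] <- tabulate(idx[best$assign == c, j], 20)
      nn <- sum(best$assign == c)
      (m + pseudocount * bg) / (nn + pseudocount)
    })
    list(assignments = best$assign, pssms = pssms, kld = best$kld, g = g)
  }

  states <- lapply(g_range, run_one)
  runs <- tibble::tibble(
    g = g_range,
    kld = vapply(states, `[[`, numeric(1), "kld")
  )
  structure(
    list(runs = runs, states = setNames(states, paste0("g", g_range)),
         selected_g = g_range[which.max(runs$kld)]),
    class = "gibbs_result"
  )
}

#' @export
print.gibbs_result <- function(x, ...) {
  cat("<gibbs_result> selected g =", x$selected_g, "\n")
  print(x$runs)
  invisible(x)
}
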