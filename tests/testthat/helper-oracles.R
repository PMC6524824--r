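# Independent oracles kept deliberately naive: they re-derive the
# statistics by direct enumeration / literal running sums, sharing no code
# with the package internals.

# ssGSEA enrichment score for one cell and one set, as a literal walk down
# the ranked list with explicit running fractions.
ssgsea_oracle_cell <- function(values, genes, set, tau) {
  obs <- !is.na(values)
  v <- values[obs]
  g <- genes[obs]
  ord <- order(-v, g)
  g <- g[ord]
  N <- length(g)
  in_set <- g %in% set
  m <- sum(in_set)
  if (m == 0 || m == N) return(NA_real_)
  w <- (N - seq_len(N) + 1)^tau
  W <- sum(w[in_set])
  es <- 0; p_in <- 0; p_out <- 0
  for (j in seq_len(N)) {
    if (in_set[j]) p_in <- p_in + w[j] / W else p_out <- p_out + 1 / (N - m)
    es <- es + (p_in - p_out)
  }
  es
}

ssgsea_oracle <- function(tbl, sets, tau) {
  genes <- tbl[[1]]
  cells <- names(tbl)[-1]
  out <- matrix(NA_real_, length(sets), length(cells),
                dimnames = list(names(sets), cells))
  for (cn in cells) {
    for (sn in names(sets)) {
      out[sn, cn] <- ssgsea_oracle_cell(tbl[[cn]], genes, sets[[sn]], tau)
    }
  }
  out
}

# Two-sided Fisher exact p by exhaustive enumeration of every table with
# the observed margins, probabilities from log-binomial coefficients.
fisher_oracle_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Fast helper used across tests: run the full gene-set pipeline on a
# simulated cohort and return truth/hit bookkeeping.
recover_signatures <- function(cohort, variable_only = TRUE) {
  pipe <- run_signature_pipeline(cohort$apa, cohort$expression,
                                 cohort$annotation, cohort$gene_sets,
                                 variable_only = variable_only)
  truth_pairs <- unlist(lapply(names(cohort$truth), function(ty) {
    paste(cohort$truth[[ty]]$sets, ty)
  }), use.names = FALSE)
  sig <- tidy(pipe$signatures)
  hit_pairs <- paste(sig$component, sig$cell_type)[sig$hit]
  list(pipeline = pipe, truth = truth_pairs, hits = hit_pairs,
       n_tested = sum(!is.na(sig$odds_ratio)))
}

small_config <- function(cells_per_type = 15, ...) {
  sim_config(n_cell_types = 3, cells_per_type = cells_per_type,
             n_genes = 300, n_gene_sets = 40, genes_per_set = c(8, 15),
             planted_sets_per_type = 2, ...)
}
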