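#' Build a ranked gene list
#'
#' Genes ordered by nonincreasing metric; ties broken lexically by symbol.
#'
#' @param genes character vector of unique symbols.
#' @param metric numeric ranking metric (e.g. log-FC or trend statistic).
#' @return a `ranked_list` data.frame with columns `gene`, `metric`.
#' @export
ranked_list <- function(genes, metric) {
  stopifnot(length(genes) == length(metric))
  if (anyDuplicated(genes)) stop("genes must be unique", call. = FALSE)
  ord <- order(-metric, genes)
  structure(data.frame(gene = genes[ord], metric = metric[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_list", "data.frame"))
}

#' Running-sum enrichment score for one gene set
#'
#' Classic weighted Kolmogorov-Smirnov statistic: walking down the ranked
#' list, the running sum increases by `|metric|^weight / sum(|metric|^weight
#' over hits)` at set genes and decreases by `1 / (N - N_hits)` at misses;
#' the enrichment score is the signed maximum deviation from zero. The
#' leading edge is the hits at or before the positive extremum (or at or
#' after the negative extremum).
#'
#' @param ranked a [ranked_list()].
#' @param gene_set character vector of symbols.
#' @param weight exponent on the metric (0 = unweighted KS, 1 = classic).
#' @return list with `es`, `leading_edge`, and the full `running` sum.
#' @export
preranked_es <- function(ranked, gene_set, weight = 1) {
  hit <- ranked$gene %in% gene_set
  n <- length(hit); nh <- sum(hit)
  if (nh == 0) stop("gene set has no overlap with the ranked list", call. = FALSE)
  if (nh == n) stop("gene set covers the whole ranked list; ES undefined",
                    call. = FALSE)
  w <- abs(ranked$metric)^weight
  inc <- numeric(n)
  denom <- sum(w[hit])
  inc[hit] <- if (denom > 0) w[hit] / denom else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  i_max <- which.max(running); i_min <- which.min(running)
  es <- if (running[i_max] >= -running[i_min]) running[i_max] else running[i_min]
  leading <- if (es >= 0) ranked$gene[seq_len(i_max)][hit[seq_len(i_max)]]
  else ranked$gene[i_min:n][hit[i_min:n]]
  list(es = es, leading_edge = leading, running = running)
}

#' Permutation significance for preranked enrichment
#'
#' Null enrichment scores are obtained by permuting gene labels (set
#' membership positions). The p value is the same-sign tail fraction of
#' null scores at least as extreme; NES divides the observed ES by the mean
#' |null ES| of the same sign; q is BH across sets.
#'
#' @param ranked a [ranked_list()].
#' @param sets named list of gene sets.
#' @param n_perm permutations per set size.
#' @param weight passed to [preranked_es()].
#' @param seed RNG seed.
#' @return data.frame per set: `set`, `es`, `nes`, `p`, `q`, `size`,
#'   `leading_edge` (comma-separated).
#' @export
preranked_significance <- function(ranked, sets, n_perm = 1000, weight = 1,
                                   seed = 1) {
  n <- nrow(ranked)
  res <- lapply(names(sets), function(nm) {
    obs <- preranked_es(ranked, sets[[nm]], weight)
    nh <- sum(ranked$gene %in% sets[[nm]])
    null_es <- withr_seed(seed + match(nm, names(sets)), {
      vapply(seq_len(n_perm), function(k) {
        pos <- sample(n, nh)
        hit <- logical(n); hit[pos] <- TRUE
        es_from_hits(ranked$metric, hit, weight)
      }, 0)
    })
    same <- null_es[sign(null_es) == sign(obs$es) | null_es == 0]
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- if (length(same) && mean(abs(same)) > 0)
      obs$es / mean(abs(same)) else NA_real_
    data.frame(set = nm, es = obs$es, nes = nes, p = p, size = nh,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[, c("set", "es", "nes", "p", "q", "size", "leading_edge")]
}

# streaming ES given a hit indicator over an already-ranked metric
es_from_hits <- function(metric, hit, weight = 1) {
  n <- length(hit); nh <- sum(hit)
  w <- abs(metric)^weight
  denom <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (denom > 0) w[hit] / denom else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  mx <- max(running); mn <- min(running)
  if (mx >= -mn) mx else mn
}
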