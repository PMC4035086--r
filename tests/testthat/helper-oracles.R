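# Independent oracles used to cross-check the package's implementations.
# Each is written as the most direct computation available (recursion,
# enumeration, literal summation), deliberately ignoring the optimised
# paths the package itself takes.

# ---- brute-force affine-gap global aligner (score only) ---------------------
# memoized recursion over (i, j, state); a gap of length L costs
# open + L * ext, matching the package's convention
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 2, ext = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == 0 && j == 0) {
      val <- 0
    } else {
      best <- -Inf
      if (i > 0 && j > 0) {
        sub <- if (a[i] == b[j]) match else mismatch
        best <- max(best, rec(i - 1, j - 1, "M") + sub)
      }
      if (i > 0) {   # gap in b
        cost <- ext + if (state != "GB") open else 0
        best <- max(best, rec(i - 1, j, "GB") - cost)
      }
      if (j > 0) {   # gap in a
        cost <- ext + if (state != "GA") open else 0
        best <- max(best, rec(i, j - 1, "GA") - cost)
      }
      val <- best
    }
    memo[[key]] <- val
    val
  }
  # states seen from the right end; start in "M" (no open gap)
  rec(length(a), length(b), "M")
}

# ---- genetic-code oracle via seqinr ----------------------------------------
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_degeneracy <- function(codon, pos) {
  aa <- oracle_translate(codon)
  n_syn <- 0L; n_nonstop <- 0L
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
    v <- codon
    substr(v, pos, pos) <- b
    vaa <- oracle_translate(v)
    if (vaa == "*") next
    n_nonstop <- n_nonstop + 1L
    if (vaa == aa) n_syn <- n_syn + 1L
  }
  c("nondegenerate", "twofold", "threefold", "fourfold")[n_syn + 1L]
}

# ---- brute-force NG86 on short codon pairs ---------------------------------
# literal enumeration: per-position synonymous fractions for sites, all
# permutations of differing positions for pathways (stop-passing pathways
# dropped; if all are blocked, all are used)
oracle_ng86 <- function(cds_a, cds_b) {
  codons <- function(s) substring(s, seq(1, nchar(s) - 2, 3),
                                  seq(3, nchar(s), 3))
  ca <- codons(cds_a); cb <- codons(cds_b)
  syn_sites <- function(cod) {
    tot <- 0
    for (pos in 1:3) {
      vs <- character(0)
      for (b in setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))) {
        v <- cod; substr(v, pos, pos) <- b; vs <- c(vs, v)
      }
      aas <- vapply(vs, oracle_translate, character(1))
      keep <- aas != "*"
      if (any(keep))
        tot <- tot + sum(aas[keep] == oracle_translate(cod)) / sum(keep)
    }
    tot
  }
  S <- (sum(vapply(ca, syn_sites, numeric(1))) +
          sum(vapply(cb, syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    out
  }
  S_sub <- 0; N_sub <- 0
  for (i in which(ca != cb)) {
    pos <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    walk <- function(ord, allow_stop) {
      cur <- ca[i]; s <- 0; n <- 0
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(cb[i], p, p)
        if (!allow_stop && oracle_translate(nxt) == "*") return(NULL)
        if (oracle_translate(nxt) == oracle_translate(cur) &&
            oracle_translate(nxt) != "*") s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    paths <- Filter(Negate(is.null), lapply(perms(pos), walk,
                                            allow_stop = FALSE))
    if (length(paths) == 0)
      paths <- lapply(perms(pos), walk, allow_stop = TRUE)
    avg <- Reduce(`+`, paths) / length(paths)
    S_sub <- S_sub + avg[1]; N_sub <- N_sub + avg[2]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, S_sub = S_sub, N_sub = N_sub,
       ks = jc(S_sub / S), ka = jc(N_sub / N))
}

# ---- hypergeometric upper tail by subset enumeration (N <= 12) -------------
oracle_hypergeom <- function(N, M, n, m) {
  hits <- combn(N, n, function(draw) sum(draw <= M) >= m)
  mean(hits)
}

# ---- Audic-Claverie by literal log-gamma summation -------------------------
# both tails are summed term by term (no 1-minus cancellation); the upper
# tail is truncated once the remaining mass is negligible
oracle_ac_p <- function(x, y, N1, N2) {
  lp <- function(k) {
    k * log(N2 / N1) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log(1 + N2 / N1)
  }
  lower <- sum(exp(lp(0:y)))
  upper <- sum(exp(lp((y + 1):(y + 5000))))
  min(1, 2 * min(lower, upper))
}

# ---- quadratic-time BH step-up reference -----------------------------------
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  adj <- numeric(n)
  for (i in seq_len(n)) {
    cand <- n * p / r
    adj[i] <- min(1, min(cand[r >= r[i]]))
  }
  adj
}

# ---- shared fixtures --------------------------------------------------------

# a random sense-codon CDS (no stops) of n_codons codons
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# one simulated CDS pair under the codon model, terminal stop removed
sim_cds_pair <- function(n_codons, omega, kappa, t, seed) {
  anc <- paste0(random_cds(n_codons, seed = seed), "TAA")
  prm <- evolution_params(omega = omega, kappa = kappa, t_cds = t,
                          t_utr = 0, seed = seed + 1L)
  ev <- evolve_ortholog(anc, 1L, 3L * (n_codons + 1L), prm)
  list(a = substr(anc, 1, 3 * n_codons),
       b = substr(ev$seq, 1, 3 * n_codons),
       truth = ev$truth)
}

# memoised cohorts so several test files can share one simulation
.cohort_cache <- new.env(parent = emptyenv())
test_cohort <- function(n_genes, seed, params = evolution_params()) {
  key <- paste(n_genes, seed, params$omega, params$t_cds)
  if (is.null(.cohort_cache[[key]])) {
    anc <- generate_ancestral_transcriptome(n_genes, seed = seed)
    params$seed <- seed + 1L
    .cohort_cache[[key]] <- list(anc = anc,
                                 cohort = evolve_transcriptome(anc, params))
  }
  .cohort_cache[[key]]
}
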