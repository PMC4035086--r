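# Ka/Ks estimation by approximate counting methods.
#
# NG86 (Nei-Gojobori 1986): synonymous/nonsynonymous sites counted with
# equal weight on the three possible changes at each position (changes to
# stop codons excluded, their weight redistributed), multi-step codon
# differences averaged over all minimal mutational pathways that avoid
# stop codons, and a Jukes-Cantor correction applied to the proportions.
#
# YN00 (Yang-Nielsen 2000 style): F3x4 codon frequencies estimated from
# the pair, transition/transversion ratio kappa estimated from K80
# distances at concordant fourfold-degenerate (synonymous) and
# nondegenerate (nonsynonymous) sites, kappa- and frequency-weighted site
# counting, pathway weights proportional to target-codon frequency x
# kappa^(transition) x omega^(nonsynonymous), and K80-style corrections
# applied separately within the synonymous and nonsynonymous classes.
# omega is updated by fixed-point iteration.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# all orderings of a position vector (<= 3 elements here)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(.perms(v[-i]), function(p) c(v[i], p))))
}

# validate and codon-split an aligned CDS pair
.kaks_codons <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    od_input_error("aligned CDSs must have equal length")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  if (length(ca) == 0L) od_input_error("empty CDS")
  if (any(codon_aa(ca) == "*") || any(codon_aa(cb) == "*"))
    od_input_error("CDSs must contain no stop codons")
  list(a = ca, b = cb)
}

# per-codon NG86 synonymous site count (sum over the 3 positions of the
# fraction of non-stop single-nucleotide changes that are synonymous)
.ng86_site_env <- new.env(parent = emptyenv())
.ng86_sites_per_codon <- function() {
  if (!is.null(.ng86_site_env$s)) return(.ng86_site_env$s)
  tab <- .codon_tables()
  sense <- tab$codons[tab$aa != "*"]
  s <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    tot <- 0
    for (pos in 1:3) {
      base <- substr(cod, pos, pos)
      variants <- vapply(setdiff(NUCS, base), function(b) {
        v <- cod; substr(v, pos, pos) <- b; v
      }, character(1))
      vaa <- codon_aa(variants)
      keep <- vaa != "*"
      if (any(keep)) tot <- tot + sum(vaa[keep] == codon_aa(cod)) / sum(keep)
    }
    s[cod] <- tot
  }
  .ng86_site_env$s <- s
  s
}

# enumerate minimal mutational pathways between two codons; returns a list
# of paths, each a data.frame of steps with syn (logical) and ts (logical);
# paths passing through a stop codon are dropped (all paths returned with
# valid = FALSE flag if every path is blocked)
.codon_paths <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- list()
  for (ord in .perms(pos)) {
    cur <- c1
    steps <- vector("list", length(ord))
    blocked <- FALSE
    for (k in seq_along(ord)) {
      p <- ord[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% STOP_CODONS) { blocked <- TRUE; break }
      steps[[k]] <- data.frame(
        from = cur, to = nxt, pos = p,
        syn = codon_aa(nxt) == codon_aa(cur),
        ts = is_transition(substr(cur, p, p), substr(nxt, p, p)))
      cur <- nxt
    }
    if (!blocked)
      paths[[length(paths) + 1L]] <- do.call(rbind, steps)
  }
  paths
}

# all pathways ignoring stop blocking (fallback when every path is blocked)
.codon_paths_all <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  lapply(.perms(pos), function(ord) {
    cur <- c1
    steps <- vector("list", length(ord))
    for (k in seq_along(ord)) {
      p <- ord[k]
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      steps[[k]] <- data.frame(
        from = cur, to = nxt, pos = p,
        syn = codon_aa(nxt) == codon_aa(cur) &
          !(nxt %in% STOP_CODONS) & !(cur %in% STOP_CODONS),
        ts = is_transition(substr(cur, p, p), substr(nxt, p, p)))
      cur <- nxt
    }
    do.call(rbind, steps)
  })
}

.new_kaks_result <- function(method, pair_id, S_sites, N_sites, S_sub, N_sub,
                             ka, ks, kappa_hat = NA_real_, flags = character(0),
                             n_codons = NA_integer_) {
  structure(list(pair_id = pair_id, method = method,
                 S_sites = S_sites, N_sites = N_sites,
                 S_sub = S_sub, N_sub = N_sub,
                 ka = ka, ks = ks,
                 ratio = if (is.na(ka) || is.na(ks) || ks == 0) NA_real_
                         else ka / ks,
                 kappa_hat = kappa_hat, flags = flags,
                 n_codons = n_codons),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result %s> Ka=%.4g Ks=%.4g Ka/Ks=%.4g (S=%.1f N=%.1f%s)\n",
              x$method, x$ka, x$ks,
              if (is.na(x$ratio)) NA else x$ratio,
              x$S_sites, x$N_sites,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Ka/Ks by the Nei-Gojobori (1986) counting method
#'
#' @param cds_a,cds_b equal-length, gap-free, in-frame aligned CDSs with no
#'   stop codons.
#' @param pair_id optional label.
#' @return a `"kaks_result"` with fractional site and substitution counts,
#'   Jukes-Cantor-corrected `ka` and `ks`, and `ratio` (`NA` when `ks` is
#'   zero or undefined).  A proportion >= 3/4 marks the result `saturated`.
#' @export
kaks_ng86 <- function(cds_a, cds_b, pair_id = NA_character_) {
  cod <- .kaks_codons(cds_a, cds_b)
  spc <- .ng86_sites_per_codon()
  n_cod <- length(cod$a)
  S <- (sum(spc[cod$a]) + sum(spc[cod$b])) / 2
  N <- 3 * n_cod - S
  S_sub <- 0; N_sub <- 0
  differ <- which(cod$a != cod$b)
  for (i in differ) {
    paths <- .codon_paths(cod$a[i], cod$b[i])
    if (length(paths) == 0L) paths <- .codon_paths_all(cod$a[i], cod$b[i])
    syn_per_path <- vapply(paths, function(p) sum(p$syn), numeric(1))
    nd <- nrow(paths[[1L]])
    S_sub <- S_sub + mean(syn_per_path)
    N_sub <- N_sub + nd - mean(syn_per_path)
  }
  pS <- S_sub / S
  pN <- N_sub / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(pS); ka <- jc(pN)
  flags <- character(0)
  if (is.na(ks) || is.na(ka)) flags <- c(flags, "saturated")
  .new_kaks_result("NG86", pair_id, S, N, S_sub, N_sub, ka, ks,
                   flags = flags, n_codons = n_cod)
}

# K80 distance decomposition from transition proportion P and transversion
# proportion Q; returns total distance d and transitional/transversional
# components A, B (NA when the logs are undefined, i.e. saturated)
.k80 <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    return(list(d = NA_real_, A = NA_real_, B = NA_real_))
  A <- -0.5 * log(a1) + 0.25 * log(a2)
  B <- -0.5 * log(a2)
  list(d = A + B, A = A, B = B)
}

# estimate kappa from concordant fourfold (synonymous) and nondegenerate
# (nonsynonymous) sites via K80; site-count-weighted average of 2A/B
.estimate_kappa <- function(ca, cb) {
  tab <- .codon_tables()
  cls_a <- matrix(tab$deg[ca, , drop = FALSE], ncol = 3L)
  cls_b <- matrix(tab$deg[cb, , drop = FALSE], ncol = 3L)
  base_a <- matrix(unlist(strsplit(ca, "")), ncol = 3L, byrow = TRUE)
  base_b <- matrix(unlist(strsplit(cb, "")), ncol = 3L, byrow = TRUE)
  one_class <- function(want) {
    sel <- cls_a == want & cls_b == want
    L <- sum(sel)
    if (L < 10L) return(NULL)                      # too few sites to inform
    diffs <- base_a[sel] != base_b[sel]
    ts <- diffs & (TRANSITION[base_a[sel]] == base_b[sel])
    P <- sum(ts) / L
    Q <- sum(diffs & !ts) / L
    k <- .k80(P, Q)
    if (is.na(k$A) || is.na(k$B) || k$B <= 0) return(NULL)
    list(kappa = 2 * k$A / k$B, L = L)
  }
  est <- Filter(Negate(is.null),
                list(one_class("fourfold"), one_class("nondegenerate")))
  if (length(est) == 0L) return(1)
  w <- vapply(est, `[[`, numeric(1), "L")
  k <- vapply(est, `[[`, numeric(1), "kappa")
  max(sum(w * k) / sum(w), 1e-3)
}

# F3x4 sense-codon frequencies from both sequences
.f3x4 <- function(ca, cb) {
  tab <- .codon_tables()
  base <- rbind(matrix(unlist(strsplit(ca, "")), ncol = 3L, byrow = TRUE),
                matrix(unlist(strsplit(cb, "")), ncol = 3L, byrow = TRUE))
  f <- vapply(1:3, function(p)
    prop.table(table(factor(base[, p], levels = NUCS))), numeric(4))
  sense <- tab$codons[tab$aa != "*"]
  pi <- vapply(sense, function(cod) {
    f[match(substr(cod, 1, 1), NUCS), 1] *
      f[match(substr(cod, 2, 2), NUCS), 2] *
      f[match(substr(cod, 3, 3), NUCS), 3]
  }, numeric(1))
  pi / sum(pi)
}

# kappa/frequency-weighted synonymous site count per codon under the
# mutation model q(i->j) ~ pi_j * kappa^(transition), stops excluded
.yn_sites <- function(codons, kappa, pi) {
  types <- table(codons)
  total_S <- 0
  for (cod in names(types)) {
    s_cod <- 0
    w_all <- 0; w_syn <- 0
    for (pos in 1:3) {
      base <- substr(cod, pos, pos)
      for (b in setdiff(NUCS, base)) {
        v <- cod; substr(v, pos, pos) <- b
        if (v %in% STOP_CODONS) next
        w <- pi[[v]] * if (is_transition(base, b)) kappa else 1
        w_all <- w_all + w
        if (codon_aa(v) == codon_aa(cod)) w_syn <- w_syn + w
      }
    }
    if (w_all > 0) s_cod <- 3 * w_syn / w_all
    total_S <- total_S + s_cod * types[[cod]]
  }
  total_S
}

# weighted difference counts (syn/nonsyn x ts/tv) for one codon pair under
# current kappa/omega; averaged over both directions for symmetry
.yn_count_pair <- function(c1, c2, kappa, omega, pi) {
  count_dir <- function(from, to) {
    paths <- .codon_paths(from, to)
    if (length(paths) == 0L) paths <- .codon_paths_all(from, to)
    w <- vapply(paths, function(p) {
      prod(pi[p$to] * ifelse(p$ts, kappa, 1) * ifelse(p$syn, 1, omega))
    }, numeric(1))
    if (all(w == 0)) w <- rep(1, length(w))
    w <- w / sum(w)
    acc <- c(syn_ts = 0, syn_tv = 0, nonsyn_ts = 0, nonsyn_tv = 0)
    for (j in seq_along(paths)) {
      p <- paths[[j]]
      acc <- acc + w[j] * c(sum(p$syn & p$ts), sum(p$syn & !p$ts),
                            sum(!p$syn & p$ts), sum(!p$syn & !p$ts))
    }
    acc
  }
  (count_dir(c1, c2) + count_dir(c2, c1)) / 2
}

#' Ka/Ks by a Yang-Nielsen (2000) style counting method
#'
#' Codon frequencies (F3x4) and the transition/transversion ratio are
#' estimated from the pair itself; sites and multi-hit pathway weights are
#' frequency- and kappa-weighted, and the correction for multiple hits is
#' applied separately within the synonymous and nonsynonymous classes.
#' The nonsynonymous/synonymous acceptance ratio omega enters the pathway
#' weights and is solved by fixed-point iteration.
#'
#' @inheritParams kaks_ng86
#' @param tol convergence tolerance on omega (default 1e-8).
#' @param max_iter maximum fixed-point iterations (default 100).
#' @return a `"kaks_result"` with `kappa_hat`; flags may include
#'   `short_alignment` (fewer than 100 codons), `saturated` and
#'   `not_converged`.
#' @export
kaks_yn00 <- function(cds_a, cds_b, pair_id = NA_character_,
                      tol = 1e-8, max_iter = 100L) {
  cod <- .kaks_codons(cds_a, cds_b)
  n_cod <- length(cod$a)
  flags <- if (n_cod < 100L) "short_alignment" else character(0)
  kappa <- .estimate_kappa(cod$a, cod$b)
  pi <- .f3x4(cod$a, cod$b)
  S <- (.yn_sites(cod$a, kappa, pi) + .yn_sites(cod$b, kappa, pi)) / 2
  N <- 3 * n_cod - S
  differ <- which(cod$a != cod$b)
  if (length(differ) == 0L)
    return(.new_kaks_result("YN00", pair_id, S, N, 0, 0, 0, 0,
                            kappa_hat = kappa, flags = flags,
                            n_codons = n_cod))
  omega <- 1
  counts <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    acc <- c(syn_ts = 0, syn_tv = 0, nonsyn_ts = 0, nonsyn_tv = 0)
    for (i in differ)
      acc <- acc + .yn_count_pair(cod$a[i], cod$b[i], kappa, omega, pi)
    counts <- acc
    ks_k <- .k80(acc[["syn_ts"]] / S, acc[["syn_tv"]] / S)
    ka_k <- .k80(acc[["nonsyn_ts"]] / N, acc[["nonsyn_tv"]] / N)
    ks <- ks_k$d; ka <- ka_k$d
    if (is.na(ks) || is.na(ka)) {
      return(.new_kaks_result("YN00", pair_id, S, N,
                              acc[["syn_ts"]] + acc[["syn_tv"]],
                              acc[["nonsyn_ts"]] + acc[["nonsyn_tv"]],
                              ka, ks, kappa_hat = kappa,
                              flags = c(flags, "saturated"),
                              n_codons = n_cod))
    }
    omega_new <- if (ks > 0) ka / ks else omega
    if (abs(omega_new - omega) < tol) { omega <- omega_new; converged <- TRUE; break }
    omega <- omega_new
    if (ks == 0) break                       # nothing left to weight by
  }
  if (!converged) flags <- c(flags, "not_converged")
  .new_kaks_result("YN00", pair_id, S, N,
                   counts[["syn_ts"]] + counts[["syn_tv"]],
                   counts[["nonsyn_ts"]] + counts[["nonsyn_tv"]],
                   ka, ks, kappa_hat = kappa, flags = flags,
                   n_codons = n_cod)
}

#' Ka/Ks for a set of ortholog pairs
#'
#' @param pairs list of `"ortholog_pair"` objects (from
#'   [partition_regions()]); pairs without a usable codon-aligned CDS are
#'   skipped.
#' @param method `"YN00"` (default) or `"NG86"`.
#' @param ... passed to the per-pair estimator.
#' @return list of `"kaks_result"` objects.
#' @export
kaks <- function(pairs, method = c("YN00", "NG86"), ...) {
  method <- match.arg(method)
  fn <- if (method == "YN00") kaks_yn00 else kaks_ng86
  res <- list()
  for (p in pairs) {
    if (nchar(p$codon_cds$a) < 3L) next
    res[[length(res) + 1L]] <- fn(p$codon_cds$a, p$codon_cds$b,
                                  pair_id = p$pair_id, ...)
  }
  res
}

#' Turn a list of Ka/Ks results into a data.frame
#' @param results list of `"kaks_result"` objects.
#' @return data.frame mirroring the per-pair output table.
#' @export
kaks_table <- function(results) {
  do.call(rbind, lapply(results, function(x)
    data.frame(pair_id = x$pair_id, method = x$method,
               S_sites = x$S_sites, N_sites = x$N_sites,
               S_sub = x$S_sub, N_sub = x$N_sub,
               Ka = x$ka, Ks = x$ks, ratio = x$ratio,
               kappa_hat = x$kappa_hat,
               flags = paste(x$flags, collapse = ","),
               stringsAsFactors = FALSE)))
}

#' Classify selection from Ka/Ks results
#'
#' Pairs with ratio below 1 are labelled `purifying`, above 1 `positive`;
#' pairs whose ratio is undefined (Ks of zero, or saturation) are labelled
#' `undefined` and excluded from the summary denominators.
#'
#' @param results list of `"kaks_result"` objects or a [kaks_table()]
#'   data.frame.
#' @return list with `calls` (data.frame `pair_id`, `ratio`, `call`) and
#'   `summary` (`n_defined`, `n_purifying`, `n_positive`,
#'   `pct_purifying`, `mean_ka`, `mean_ks`, `mean_ratio` over pairs with
#'   both rates defined).
#' @export
classify_selection <- function(results) {
  tab <- if (is.data.frame(results)) results else kaks_table(results)
  defined <- !is.na(tab$ratio)
  call <- ifelse(!defined, "undefined",
                 ifelse(tab$ratio > 1, "positive",
                        ifelse(tab$ratio < 1, "purifying", "undefined")))
  d <- tab[defined, , drop = FALSE]
  list(calls = data.frame(pair_id = tab$pair_id, ratio = tab$ratio,
                          call = call, stringsAsFactors = FALSE),
       summary = data.frame(
         n_defined = nrow(d),
         n_purifying = sum(call == "purifying"),
         n_positive = sum(call == "positive"),
         pct_purifying = if (nrow(d)) 100 * sum(d$ratio < 1) / nrow(d)
                         else NA_real_,
         mean_ka = if (nrow(d)) mean(d$Ka) else NA_real_,
         mean_ks = if (nrow(d)) mean(d$Ks) else NA_real_,
         mean_ratio = if (nrow(d)) mean(d$ratio) else NA_real_))
}
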