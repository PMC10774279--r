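# shared fixtures and independent brute-force oracles

small_train_spec <- function(rng_seed = 7L, coupling = c(UD = 0.2, BD = 0.6),
                             n = c(UD = 10L, BD = 10L)) {
  cohort_spec(grid_shape = c(6L, 6L, 4L), n_regions = 6L,
              seed_region_ids = 1L, planted_region_ids = c(3L, 5L),
              n_per_group = n,
              coupling_by_group = c(coupling, tBD = unname(
                if ("tBD" %in% names(coupling)) coupling[["tBD"]] else 0.6)),
              baseline_coupling = 0.2, noise_sd = 1,
              n_timepoints = 120L, tr_seconds = 2, rng_seed = rng_seed)
}

# breadth-first connectivity of one region under 6-neighbourhood adjacency
region_is_contiguous <- function(labels, id) {
  co <- which(labels == id, arr.ind = TRUE)
  if (nrow(co) == 0L) return(FALSE)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  all_keys <- key(co)
  seen <- structure(logical(nrow(co)), names = all_keys)
  queue <- all_keys[1]
  seen[queue] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  co_map <- stats::setNames(seq_len(nrow(co)), all_keys)
  while (length(queue) > 0L) {
    cur <- co[co_map[queue[1]], , drop = FALSE]
    queue <- queue[-1]
    nb <- sweep(shifts, 2L, as.numeric(cur), `+`)
    nb_keys <- key(nb)
    hit <- nb_keys[nb_keys %in% all_keys & !seen[nb_keys]]
    if (length(hit) > 0L) {
      seen[hit] <- TRUE
      queue <- c(queue, hit)
    }
  }
  all(seen)
}

# exact two-sided Mann-Whitney p by enumerating every group assignment
oracle_mann_whitney <- function(a, b) {
  na <- length(a)
  all_v <- c(a, b)
  n <- length(all_v)
  rk <- rank(all_v)
  u_of <- function(idx) sum(rk[idx]) - na * (na + 1) / 2
  mu <- na * (n - na) / 2
  obs <- abs(u_of(seq_len(na)) - mu)
  combos <- utils::combn(n, na)
  dev <- apply(combos, 2L, function(idx) abs(u_of(idx) - mu))
  mean(dev >= obs - 1e-9)
}

# exact Freeman-Halton p by enumerating all tables with the observed margins
oracle_freeman_halton <- function(counts) {
  rs <- rowSums(counts); cs <- colSums(counts)
  lp_table <- function(tab)
    sum(lfactorial(rs)) + sum(lfactorial(cs)) -
      lfactorial(sum(tab)) - sum(lfactorial(tab))
  tables <- list()
  fill_row <- function(partial, row, rem_cols) {
    if (row == length(rs)) {
      if (all(rem_cols >= 0)) tables[[length(tables) + 1L]] <<-
          rbind(partial, rem_cols)
      return(invisible())
    }
    cells <- function(prefix, j, rem_row) {
      if (j == length(cs)) {
        if (rem_row <= rem_cols[j]) {
          fill_row(rbind(partial, c(prefix, rem_row)), row + 1L,
                   rem_cols - c(prefix, rem_row))
        }
        return(invisible())
      }
      for (v in 0:min(rem_row, rem_cols[j]))
        cells(c(prefix, v), j + 1L, rem_row - v)
    }
    cells(integer(0), 1L, rs[row])
  }
  fill_row(NULL, 1L, cs)
  lp_obs <- lp_table(counts)
  lps <- vapply(tables, lp_table, numeric(1))
  sum(exp(lps)[lps <= lp_obs + 1e-7])
}

# AUC as the pairwise win probability estimator
oracle_auc <- function(scores, labels, positive_class) {
  sp <- scores[labels == positive_class]
  sn <- scores[labels != positive_class]
  wins <- outer(sp, sn, `>`)
  ties <- outer(sp, sn, `==`)
  (sum(wins) + 0.5 * sum(ties)) / (length(sp) * length(sn))
}

# BH step-up straight from the definition
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) / m * q)
  rejected <- logical(m)
  if (length(ok) > 0L) rejected[ord[seq_len(max(ok))]] <- TRUE
  adj <- rev(cummin(rev(ps * m / seq_len(m))))
  adjusted <- numeric(m)
  adjusted[ord] <- pmin(adj, 1)
  list(rejected = rejected, p_adjusted = adjusted)
}
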