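# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: masses are re-typed literals, formula
# enumeration is a full grid over ALL elements (H included), and quartet
# matching is a naive all-pairs scan with no sorted-search shortcuts.

ORC <- list(C = 12, H = 1.00782503207, N = 14.0030740048, O = 15.99491461956,
            P = 30.97376163, S = 31.97207100,
            C13 = 13.0033548378, N15 = 15.0001088982,
            proton = 1.00727646677)

oracle_mass <- function(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  C * ORC$C + H * ORC$H + N * ORC$N + O * ORC$O + P * ORC$P + S * ORC$S

# Full nested enumeration over H, O, P, S with c and n fixed (expressed as
# one exhaustive grid); mirrors the spec'd plausibility filters directly.
oracle_decompose <- function(neutral_mass, c, n, tol_ppm, bounds = element_bounds()) {
  g <- expand.grid(h = bounds$H[1]:bounds$H[2], o = bounds$O[1]:bounds$O[2],
                   p = bounds$P[1]:bounds$P[2], s = bounds$S[1]:bounds$S[2])
  mass <- oracle_mass(c, g$h, n, g$o, g$p, g$s)
  ppm <- (mass - neutral_mass) / neutral_mass * 1e6
  rd <- c + 1 + (n + g$p) / 2 - g$h / 2
  hc_ok <- if (c == 0) rep(TRUE, nrow(g)) else
    g$h / c >= bounds$hc_ratio_range[1] & g$h / c <= bounds$hc_ratio_range[2]
  ok <- abs(ppm) <= tol_ppm &
    rd >= bounds$rdbe_range[1] & rd <= bounds$rdbe_range[2] &
    abs(rd - round(rd)) < 1e-9 & hc_ok
  out <- data.frame(C = c, H = g$h[ok], N = n, O = g$o[ok], P = g$p[ok],
                    S = g$s[ok], ppm = ppm[ok])
  hetero <- out$N + out$O + out$P + out$S
  out <- out[order(abs(out$ppm), hetero, out$O, out$P, out$S), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force quartet matching: for each unlabeled peak (descending
# intensity), every (c, n, partner-peak) combination is scanned naively and
# scored by (support desc, worst ppm asc, c, n); partners are claimed
# greedily like the spec prescribes.
oracle_match_quartets <- function(u, c13, n15, dual, cfg) {
  pol <- attr(u, "polarity")
  scan <- function(set, claimed, pred, urt, uint) {
    best <- NA_integer_; bppm <- NA_real_
    for (j in seq_len(nrow(set))) {
      if (claimed[j]) next
      e <- (set$mz[j] - pred) / pred * 1e6
      if (abs(e) > cfg$mz_tol_ppm) next
      if (abs(set$rt[j] - urt) > cfg$rt_tol) next
      r <- set$intensity[j] / uint
      if (r < cfg$intensity_ratio_bounds[1] || r > cfg$intensity_ratio_bounds[2]) next
      if (is.na(best) || abs(e) < abs(bppm)) { best <- j; bppm <- e }
    }
    list(idx = best, ppm = bppm)
  }
  cl13 <- logical(nrow(c13)); cl15 <- logical(nrow(n15)); clD <- logical(nrow(dual))
  rows <- list()
  for (i in order(-u$intensity, u$mz)) {
    umz <- u$mz[i]; urt <- u$rt[i]; uint <- u$intensity[i]
    M <- if (pol == "negative") umz + ORC$proton else umz - ORC$proton
    cand <- list()
    for (cc in 0:min(cfg$c_max, floor(M / 12))) {
      hc <- scan(c13, cl13, umz + cc * (ORC$C13 - ORC$C), urt, uint)
      for (nn in 0:min(cfg$n_max, floor(M / 14))) {
        hn <- scan(n15, cl15, umz + nn * (ORC$N15 - ORC$N), urt, uint)
        hd <- scan(dual, clD,
                   umz + cc * (ORC$C13 - ORC$C) + nn * (ORC$N15 - ORC$N),
                   urt, uint)
        np <- sum(!is.na(c(hc$idx, hn$idx, hd$idx)))
        if (np == 0) next
        cand[[length(cand) + 1L]] <- list(
          c = cc, n = nn, i13 = hc$idx, i15 = hn$idx, id = hd$idx,
          support = np,
          res = max(abs(c(hc$ppm, hn$ppm, hd$ppm)), na.rm = TRUE))
      }
    }
    if (!length(cand)) next
    sup <- vapply(cand, `[[`, numeric(1), "support")
    res <- vapply(cand, `[[`, numeric(1), "res")
    cv <- vapply(cand, `[[`, numeric(1), "c")
    nv <- vapply(cand, `[[`, numeric(1), "n")
    o <- order(-sup, res, cv, nv)
    b <- cand[[o[1]]]
    amb <- length(o) > 1 && sup[o[2]] == sup[o[1]] &&
      abs(res[o[2]] - res[o[1]]) < 1e-6
    if (!is.na(b$i13)) cl13[b$i13] <- TRUE
    if (!is.na(b$i15)) cl15[b$i15] <- TRUE
    if (!is.na(b$id))  clD[b$id] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      u_mz = umz, rt = urt, c = b$c, n = b$n,
      support = c("pair", "triad", "full")[b$support],
      ppm_residual = b$res,
      mz_13c = if (is.na(b$i13)) NA_real_ else c13$mz[b$i13],
      mz_15n = if (is.na(b$i15)) NA_real_ else n15$mz[b$i15],
      mz_dual = if (is.na(b$id)) NA_real_ else dual$mz[b$id],
      ambiguous = amb, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(u_mz = numeric(0), rt = numeric(0), c = integer(0),
               n = integer(0), support = character(0),
               ppm_residual = numeric(0), mz_13c = numeric(0),
               mz_15n = numeric(0), mz_dual = numeric(0),
               ambiguous = logical(0))
  out <- out[order(out$u_mz, out$rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
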