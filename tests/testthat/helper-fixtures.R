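# Shared fixtures: small synthetic cohorts built in code at test time.

make_valid <- function(i, side = "L", subject = sprintf("S%03d", i),
                       condition = "static", noise_sd = 0.10) {
  params <- foot_shape_params(seed = 40000 + i, noise_sd = noise_sd)
  simulate_valid_foot(params, side, subject, condition = condition,
                      seed = 50000 + i)
}

# a small mixed dataset with all five labels, several subjects
small_mixed_dataset <- function(n_subjects = 12, target = 8, seed = 99) {
  simulate_dataset(n_subjects = n_subjects, seed = seed, target = target)
}

# brute-force two-tailed empirical p-value (independent of the package path)
oracle_pvalue <- function(t, x) {
  n <- length(x)
  ph <- (1 + length(which(x >= t))) / (n + 1)
  pl <- (1 + length(which(x <= t))) / (n + 1)
  min(1, 2 * min(ph, pl))
}

# flood-fill connected components, written plainly as an oracle
oracle_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nb <- if (connectivity == 8) {
    cbind(c(-1,-1,-1,0,0,1,1,1), c(-1,0,1,-1,1,-1,0,1))
  } else {
    cbind(c(-1,0,0,1), c(0,-1,1,0))
  }
  cur <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r, c)); lab[r, c] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}
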