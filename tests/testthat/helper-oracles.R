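# Independent brute-force oracles. Each one recomputes a quantity by the most
# literal possible route, sharing no code with the package implementation.

# BH step-up by the definition: sort, q_(i) = min_{j>=i} p_(j) * m / j, cap 1.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# KS D via stats::ks.test (different code path: sorted-rank C routine).
oracle_ks_D <- function(a, b) {
  suppressWarnings(unname(stats::ks.test(a, b)$statistic))
}

# Exact KS p by full enumeration of all label assignments of the pooled
# sample (the conditional permutation distribution, ties respected).
oracle_ks_exact_p <- function(a, b) {
  dstat <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
  }
  z <- c(a, b)
  na <- length(a)
  d0 <- dstat(a, b)
  idx <- utils::combn(length(z), na)
  ds <- apply(idx, 2, function(i) dstat(z[i], z[-i]))
  mean(ds >= d0 - 1e-12)
}

# Exact two-group permutation p for a location difference (all label splits),
# used as an independent check that tiny-variance separations test small.
oracle_perm_p <- function(a, b) {
  z <- c(a, b)
  na <- length(a)
  d0 <- abs(mean(a) - mean(b))
  idx <- utils::combn(length(z), na)
  ds <- apply(idx, 2, function(i) abs(mean(z[i]) - mean(z[-i])))
  mean(ds >= d0 - 1e-12)
}

# Dense-matrix propagation oracle: gene indicator -> reaction incidence
# product -> |S| support.
oracle_gem_propagation <- function(model, genes) {
  g_univ <- model$genes
  rids <- names(model$reactions)
  mids <- model$metabolites$id
  RG <- matrix(0L, nrow = length(rids), ncol = length(g_univ),
               dimnames = list(rids, g_univ))
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (r in rids) {
    RG[r, model$reactions[[r]]$genes] <- 1L
    st <- model$reactions[[r]]$stoich
    S[names(st), r] <- st
  }
  gvec <- as.integer(g_univ %in% genes)
  rvec <- as.integer((RG %*% gvec) > 0)
  mvec <- (abs(S) %*% rvec) > 0
  list(reactions = rids[rvec == 1L], metabolites = mids[mvec])
}

# Character-walk formula oracle without regular expressions: linear scan
# distinguishing upper, lower, digit and residue characters by charmatch.
oracle_parse_formula <- function(text) {
  upper <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
  lower <- strsplit("abcdefghijklmnopqrstuvwxyz", "")[[1]]
  digits <- strsplit("0123456789", "")[[1]]
  chars <- strsplit(text, "")[[1]]
  counts <- list()
  generic <- FALSE
  i <- 1
  while (i <= length(chars)) {
    sym <- chars[i]; i <- i + 1
    if (sym == "*") { generic <- TRUE; next }
    if (i <= length(chars) && chars[i] %in% lower) {
      sym <- paste0(sym, chars[i]); i <- i + 1
    }
    num <- ""
    while (i <= length(chars) && chars[i] %in% digits) {
      num <- paste0(num, chars[i]); i <- i + 1
    }
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (sym %in% c("R", "X")) { generic <- TRUE; next }
    counts[[sym]] <- (if (is.null(counts[[sym]])) 0L else counts[[sym]]) + n
  }
  list(counts = unlist(counts), generic = generic)
}

# Brute-force Venn region enumeration over three sets.
oracle_venn <- function(a, b, c_) {
  u <- unique(c(a, b, c_))
  inA <- u %in% a; inB <- u %in% b; inC <- u %in% c_
  k <- inA + inB + inC
  list(union = length(u),
       exactly_one = sum(k == 1),
       exactly_two = sum(k == 2),
       triple = sum(k == 3),
       only_a = sum(inA & !inB & !inC),
       only_b = sum(!inA & inB & !inC),
       only_c = sum(!inA & !inB & inC))
}

# Random formula generator for the parser property test.
random_formula <- function() {
  pool <- c("C", "H", "O", "N", "P", "S", "Na", "Cl", "Fe", "Mg")
  k <- sample(1:5, 1)
  syms <- sample(pool, k)
  counts <- sample(1:99, k, replace = TRUE)
  parts <- paste0(syms, ifelse(stats::runif(k) < 0.3, "", counts))
  extra <- if (stats::runif(1) < 0.25) sample(c("R", "X", "R2"), 1) else ""
  paste0(paste(parts, collapse = ""), extra)
}
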