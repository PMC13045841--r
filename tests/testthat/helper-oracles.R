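# Independent brute-force oracles, implemented with plain loops and kept
# deliberately separate from the package's vectorized code paths.

# Multi-head attention, one query position and one head at a time.
oracle_attention <- function(Q_in, KV_in, p) {
  d <- ncol(p$Wq)
  h <- p$h
  dk <- d %/% h
  Lq <- nrow(Q_in)
  Lk <- nrow(KV_in)
  H <- matrix(0, Lq, d)
  for (i in seq_len(h)) {
    cols <- ((i - 1) * dk + 1):(i * dk)
    for (q in seq_len(Lq)) {
      scores <- numeric(Lk)
      for (kk in seq_len(Lk)) {
        qv <- as.numeric(Q_in[q, ] %*% p$Wq[, cols])
        kv <- as.numeric(KV_in[kk, ] %*% p$Wk[, cols])
        scores[kk] <- sum(qv * kv) / sqrt(dk)
      }
      a <- exp(scores - max(scores))
      a <- a / sum(a)
      acc <- numeric(dk)
      for (kk in seq_len(Lk)) {
        vv <- as.numeric(KV_in[kk, ] %*% p$Wv[, cols])
        acc <- acc + a[kk] * vv
      }
      H[q, cols] <- acc
    }
  }
  H %*% p$Wo
}

# Mann-Whitney AUC by explicit pair counting.
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) {
    for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
  }
  tot / (length(pos) * length(neg))
}

# Silhouette by definition, point by point.
oracle_silhouette <- function(points, labels) {
  n <- nrow(points)
  dist_ij <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, dist_ij, 0, i = i))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, dist_ij, 0, i = i)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Calinski-Harabasz by definition.
oracle_chi <- function(points, labels) {
  cls <- unique(labels)
  K <- length(cls)
  n <- nrow(points)
  c_all <- colMeans(points)
  B <- 0
  W <- 0
  for (cl in cls) {
    P <- points[labels == cl, , drop = FALSE]
    ck <- colMeans(P)
    B <- B + nrow(P) * sum((ck - c_all)^2)
    for (i in seq_len(nrow(P))) W <- W + sum((P[i, ] - ck)^2)
  }
  (B / (K - 1)) / (W / (n - K))
}

# Character-scan SMILES tokenizer (no regex), for cross-checking the
# package's regex-based tokenizer.
oracle_smiles_tokens <- function(s) {
  chars <- strsplit(s, "")[[1]]
  toks <- character(0)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (chars[j] != "]") j <- j + 1
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else if (ch %in% c("C", "B") && i < length(chars) &&
               chars[i + 1] %in% c("l", "r") &&
               paste0(ch, chars[i + 1]) %in% c("Cl", "Br")) {
      toks <- c(toks, paste0(ch, chars[i + 1]))
      i <- i + 2
    } else {
      toks <- c(toks, ch)
      i <- i + 1
    }
  }
  toks
}

# Planted binding rule re-implemented with explicit loops.
oracle_binding <- function(tcr, pep, k) {
  tab <- residue_pairing()
  np <- nchar(pep)
  for (s in seq_len(np - k + 1)) {
    motif <- substr(pep, s, s + k - 1)
    comp <- paste(tab[strsplit(motif, "")[[1]]], collapse = "")
    for (t in seq_len(nchar(tcr) - k + 1)) {
      if (substr(tcr, t, t + k - 1) == comp) return(1L)
    }
  }
  0L
}

random_attention_params <- function(d, h, seed) {
  set.seed(seed)
  list(Wq = matrix(rnorm(d * d), d, d), Wk = matrix(rnorm(d * d), d, d),
       Wv = matrix(rnorm(d * d), d, d), Wo = matrix(rnorm(d * d), d, d),
       h = h)
}
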