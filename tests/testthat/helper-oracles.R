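# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the functions they verify.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- naive six-frame translator -------------------------------------------
.codon_table <- local({
  tb <- NULL
  function() {
    if (is.null(tb)) {
      bases <- c("T", "C", "A", "G")
      codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
      aas <- strsplit(paste0(
        "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
      # codon order above is T/C/A/G by first base slowest: build properly
      codons <- c()
      for (b1 in bases) for (b2 in bases) for (b3 in bases) {
        codons <- c(codons, paste0(b1, b2, b3))
      }
      tb <<- stats::setNames(aas, codons)
    }
    tb
  }
})

naive_translate <- function(nt) {
  n <- floor(nchar(nt) / 3)
  if (n == 0) return("")
  cods <- substring(nt, 3 * (1:n) - 2, 3 * (1:n))
  aa <- .codon_table()[cods]
  aa[is.na(aa)] <- "X"  # any codon containing N/other
  paste(aa, collapse = "")
}

naive_revcomp <- function(nt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(nt, "")[[1]]]), collapse = "")
}

# All six-frame ORFs of length >= min_len, as a data frame comparable
# with six_frame_orfs() output (forward-strand 0-based half-open).
naive_six_frame <- function(bases, min_len = 25) {
  L <- nchar(bases)
  out <- list()
  for (strand in c(1, -1)) {
    s <- if (strand == 1) bases else naive_revcomp(bases)
    for (f in 1:3) {
      aa <- naive_translate(substr(s, f, nchar(s)))
      if (nchar(aa) == 0) next
      parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 0L
      for (p in parts) {
        i1 <- pos + 1L; i2 <- pos + nchar(p)
        pos <- i2 + 1L
        if (nchar(p) < min_len) next
        s0 <- (f - 1L) + 3L * (i1 - 1L)
        e0 <- (f - 1L) + 3L * i2
        if (strand == 1) {
          out[[length(out) + 1L]] <- data.frame(
            frame = f, start = s0, end = e0, residues = p)
        } else {
          out[[length(out) + 1L]] <- data.frame(
            frame = -f, start = L - e0, end = L - s0, residues = p)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), residues = character()))
  }
  do.call(rbind, out)
}

random_contig <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- dense-matrix MCL oracle ----------------------------------------------
dense_mcl_partition <- function(edges, inflation = 1.5, prune = 1e-5,
                                tol = 1e-6, max_iter = 200) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    A[edges$a[r], edges$b[r]] <- edges$weight[r]
    A[edges$b[r], edges$a[r]] <- edges$weight[r]
  }
  diag(A) <- apply(A, 1, max)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2, pmax(colSums(M2), .Machine$double.eps), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  P <- (M >= prune)
  P <- P | t(P)
  comp <- rep(NA_integer_, n)
  k <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1
    frontier <- s
    comp[s] <- k
    while (length(frontier) > 0) {
      nbr <- which(colSums(P[frontier, , drop = FALSE]) > 0)
      nbr <- nbr[is.na(comp[nbr])]
      comp[nbr] <- k
      frontier <- nbr
    }
  }
  stats::setNames(comp, nodes)
}

# partition comparison up to label renaming
same_partition <- function(p1, p2) {
  p1 <- p1[sort(names(p1))]; p2 <- p2[sort(names(p2))]
  length(p1) == length(p2) &&
    all(names(p1) == names(p2)) &&
    identical(as.integer(factor(p1, levels = unique(p1)))
              , as.integer(factor(p2, levels = unique(p2))))
}

# --- LCA oracle: common ancestor of maximal depth -------------------------
naive_lca <- function(taxids, taxonomy) {
  anc_set <- function(t) {
    path <- t
    while (TRUE) {
      p <- taxonomy$parent[match(path[length(path)], taxonomy$taxid)]
      if (p == path[length(path)]) break
      path <- c(path, p)
    }
    path
  }
  depth <- function(t) length(anc_set(t))
  common <- Reduce(intersect, lapply(taxids, anc_set))
  common[which.max(vapply(common, depth, numeric(1)))]
}

# --- exhaustive binomial upper tail ---------------------------------------
enum_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

# --- adjusted Rand index (for recovery checks) ----------------------------
rand_ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# --- naive affine-gap Smith-Waterman on sequences -------------------------
naive_sw_score <- function(s1, s2, go = 11, ge = 1) {
  sub <- get_blosum()
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

get_blosum <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

mutate_protein <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste(ch, collapse = "")
}
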