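# Shared fixtures and independent oracles, built in code at test time.

random_dna <- function(n, L, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
}

# Brute-force k-mer encoder: enumerates all 4^h k-mers lexicographically and
# matches each window by string comparison. Independent of encode_kmer.
oracle_kmer <- function(sequence, h) {
  bases <- c("A", "C", "G", "T")
  kmers <- ""
  for (i in seq_len(h)) kmers <- as.vector(outer(kmers, bases, paste0))
  kmers <- sort(kmers) # lexicographic order
  L <- nchar(sequence)
  out <- matrix(0, 4^h, L)
  for (i in seq_len(L)) {
    if (i + h - 1 > L) next
    word <- substr(sequence, i, i + h - 1)
    j <- match(word, kmers)
    if (!is.na(j)) out[j, i] <- 1
  }
  out
}

# Independent shape oracle: direct per-position pentamer lookup, pairwise
# smoothing of the step features, then zero padding.
oracle_shape <- function(sequence, table) {
  n <- nchar(sequence)
  tab <- unclass(table)
  rc1 <- function(p) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(p, "")[[1]]]), collapse = "")
  }
  look <- function(p) {
    if (p %in% rownames(tab)) tab[p, ] else tab[rc1(p), ]
  }
  vals <- t(vapply(seq_len(n - 4), function(i) {
    look(substr(sequence, i, i + 4))
  }, numeric(4)))
  out <- matrix(0, 4, n, dimnames = list(c("MGW", "ProT", "HelT", "Roll"),
                                         NULL))
  out["MGW", 3:(n - 2)] <- vals[, "MGW"]
  out["ProT", 3:(n - 2)] <- vals[, "ProT"]
  for (f in c("HelT", "Roll")) {
    r <- vals[, f]
    k <- length(r)
    sm <- vapply(seq_len(k), function(i) {
      if (i < k) (r[i] + r[i + 1]) / 2 else r[i]
    }, numeric(1))
    out[f, 3:(n - 2)] <- sm
  }
  out
}

# O(n^2) pairwise-concordance auROC, the textbook definition.
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

count_dinucs <- function(sequences) {
  tab <- table(unlist(lapply(sequences, function(s) {
    substring(s, 1:(nchar(s) - 1), 2:nchar(s))
  })))
  tab[order(names(tab))]
}

# A tiny synthetic dataset + fitted model, shared by interpret/eval tests.
# Memoised so the training cost is paid once per test run.
tiny_fit_cache <- new.env(parent = emptyenv())

tiny_trained_fit <- function() {
  if (!is.null(tiny_fit_cache$fit)) {
    return(list(fit = tiny_fit_cache$fit, dataset = tiny_fit_cache$ds,
                table = tiny_fit_cache$st))
  }
  spec <- synthetic_spec(n_cells = 2, n_shared_pos = 150, n_neg = 150,
                         seed = 41)
  ds <- split_dataset(generate_dataset(spec), c(0.7, 0.15, 0.15), seed = 42)
  st <- make_shape_table(1)
  fit <- tfgate_fit(ds, tfgate_config(n_cells = 2, n_kernels = 8),
                    shape_table = st,
                    control = tfgate_train_control(batch_size = 16,
                                                   max_epochs = 20,
                                                   patience = Inf,
                                                   seed = 43))
  tiny_fit_cache$fit <- fit
  tiny_fit_cache$ds <- ds
  tiny_fit_cache$st <- st
  list(fit = fit, dataset = ds, table = st)
}
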