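test_that("peak centring follows the midpoint rule", {
  w <- extract_window(1000, 1200, L = 101)
  expect_equal(w$start, 1050)
  expect_equal(w$end, 1151)
  set.seed(3)
  st <- sample.int(1e6, 50)
  en <- st + sample.int(500, 50)
  ws <- extract_window(st, en)
  expect_true(all(ws$end - ws$start == 101))
  expect_equal(ws$center, (st + en) %/% 2)
  expect_error(extract_window(10, 10), "non-empty")
})

test_that("60/20/20 split has the stated sizes with remainder to train", {
  spec <- synthetic_spec(n_cells = 1, n_shared_pos = 50, n_neg = 50, seed = 1)
  ds100 <- generate_dataset(spec)
  sp <- dataset_split(split_dataset(ds100, seed = 4))
  expect_equal(lengths(sp), c(train = 60L, valid = 20L, test = 20L))
  ds101 <- generate_dataset(synthetic_spec(n_cells = 1, n_shared_pos = 51,
                                           n_neg = 50, seed = 1))
  sp101 <- dataset_split(split_dataset(ds101, seed = 4))
  expect_equal(lengths(sp101), c(train = 61L, valid = 20L, test = 20L))
})

test_that("splits are disjoint, exhaustive and seed-reproducible", {
  spec <- synthetic_spec(n_cells = 1, n_shared_pos = 12, n_neg = 11, seed = 2)
  ds <- generate_dataset(spec)
  for (seed in 1:5) {
    sp <- dataset_split(split_dataset(ds, seed = seed))
    all_idx <- sort(unname(unlist(sp)))
    expect_equal(all_idx, seq_len(nrow(ds)))
    expect_equal(sum(lengths(sp)), nrow(ds))
  }
  s1 <- dataset_split(split_dataset(ds, seed = 9))
  s2 <- dataset_split(split_dataset(ds, seed = 9))
  expect_identical(s1, s2)
})

test_that("shared/specific classification applies the >75% identity rule", {
  shared <- classify_shared_specific(
    generate_shared_specific_pair(n_pairs = 15, identity = 76 / 101, seed = 8))
  expect_true(all(shared$tag == "shared"))
  expect_true(all(shared$best_identity > 0.75))
  spec <- classify_shared_specific(
    generate_shared_specific_pair(n_pairs = 15, identity = 75 / 101, seed = 8))
  expect_true(all(spec$tag == "specific"))
  ident <- classify_shared_specific(
    generate_shared_specific_pair(n_pairs = 5, identity = 1, seed = 8))
  expect_true(all(ident$tag == "shared"))
  none <- classify_shared_specific(
    generate_shared_specific_pair(n_pairs = 5, identity = 0, seed = 8))
  expect_true(all(none$tag == "specific"))
})

test_that("classification is invariant to sample order and symmetric", {
  ds <- generate_shared_specific_pair(n_pairs = 10, identity = 0.8, seed = 3)
  tags <- classify_shared_specific(ds)
  perm <- sample(nrow(ds))
  ds_perm <- ds[perm, ]
  attr(ds_perm, "split") <- NULL
  tags_perm <- classify_shared_specific(ds_perm)
  merged <- merge(as.data.frame(tags), as.data.frame(tags_perm),
                  by = c("id", "cell_type"))
  expect_equal(merged$tag.x, merged$tag.y)
  expect_equal(merged$best_identity.x, merged$best_identity.y)
  # pairwise identity is symmetric: both members of a pair get the same tag
  ids_a <- sprintf("pair%04d_a", 1:10)
  ids_b <- sprintf("pair%04d_b", 1:10)
  expect_equal(tags$tag[match(ids_a, tags$id)],
               tags$tag[match(ids_b, tags$id)])
})

test_that("a multi-label window is shared by construction", {
  L <- 101
  seqs <- random_dna(3, L)
  samples <- tibble::tibble(
    id = c("s1", "s2", "s3"), chrom = "chr1",
    start = c(0, 500, 1000), end = c(0, 500, 1000) + L,
    sequence = seqs,
    labels = list(c(a = 1L, b = 1L), c(a = 1L, b = 0L), c(a = 0L, b = 1L)),
    histone = replicate(3, matrix(0, 8, L + 100,
                                  dimnames = list(histone_marks(), NULL)),
                        simplify = FALSE),
    is_positive = TRUE)
  ds <- new_tfgate_dataset(samples, c("a", "b"), L)
  tags <- classify_shared_specific(ds)
  expect_equal(tags$tag[tags$id == "s1"], c("shared", "shared"))
  # s2/s3 are random 101-mers: identity ~25%, so specific
  expect_equal(tags$tag[tags$id == "s2"], "specific")
})

test_that("dinucleotide shuffling preserves dinucleotide counts exactly", {
  set.seed(21)
  for (s in random_dna(10, 60)) {
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(count_dinucs(sh), count_dinucs(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 60, 60), substr(s, 60, 60))
  }
  expect_equal(dinucleotide_shuffle("AAAA"), "AAAA")
})

test_that("multi-task dataset assembly labels windows by per-cell overlap", {
  set.seed(33)
  genome <- c(chr1 = random_dna(1, 5000), chr2 = random_dna(1, 3000))
  peak <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2200L)
  other <- tibble::tibble(chrom = "chr2", start = 1000L, end = 1150L)
  ds1 <- build_multitask_dataset(list(k562 = peak), genome,
                                 negative_ratio = 0)
  expect_equal(nrow(ds1), 1L)
  expect_equal(ds1$labels[[1]], c(k562 = 1L))
  expect_equal(nchar(ds1$sequence), 101L)
  # identical peak in 2 of 3 cell types
  ds3 <- build_multitask_dataset(
    list(a = peak, b = peak, c = other), genome, negative_ratio = 0)
  labs <- do.call(rbind, ds3$labels)
  expect_equal(sort(apply(labs, 1, paste, collapse = "")),
               sort(c("110", "001")))
  expect_error(build_multitask_dataset(
    list(a = peak, b = peak[0, ]), genome), "at least one peak")
})

test_that("near-duplicate windows merge and out-of-bounds windows drop", {
  set.seed(34)
  genome <- c(chr1 = random_dna(1, 4000))
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(1000L, 1040L, 1200L, 3990L),
                          end = c(1100L, 1140L, 1300L, 4100L))
  expect_warning(
    ds <- build_multitask_dataset(list(a = peaks), genome,
                                  negative_ratio = 0),
    "chromosome bounds")
  # windows at centres 1050/1090 overlap reciprocally > 50% -> merged;
  # the 3990-4100 peak centres past the chromosome end -> dropped
  expect_equal(nrow(ds), 2L)
})

test_that("dinucleotide-shuffled negatives match positive composition", {
  set.seed(35)
  genome <- c(chr1 = random_dna(1, 60000))
  starts <- seq(500L, 55000L, by = 545L)[1:100]
  peaks <- tibble::tibble(chrom = "chr1", start = starts,
                          end = starts + 180L)
  ds <- build_multitask_dataset(list(a = peaks), genome,
                                negatives_mode = "dinucleotide_shuffle",
                                seed = 6)
  pos <- count_dinucs(ds$sequence[ds$is_positive])
  neg <- count_dinucs(ds$sequence[!ds$is_positive])
  expect_equal(as.vector(pos / sum(pos)), as.vector(neg / sum(neg)),
               tolerance = 0.01)
  expect_true(all(vapply(ds$labels[!ds$is_positive], sum, 0L) == 0L))
})

test_that("random genomic negatives avoid peaks", {
  set.seed(36)
  genome <- c(chr1 = random_dna(1, 20000))
  peaks <- tibble::tibble(chrom = "chr1", start = c(5000L, 9000L),
                          end = c(5200L, 9200L))
  ds <- build_multitask_dataset(list(a = peaks), genome,
                                negatives_mode = "random_genomic",
                                negative_ratio = 3, seed = 6)
  neg <- ds[!ds$is_positive, ]
  expect_equal(nrow(neg), 6L)
  for (i in seq_len(nrow(neg))) {
    expect_true(neg$end[i] <= 5000 || neg$start[i] >= 5200 ||
                  neg$end[i] <= 9000 || neg$start[i] >= 9200)
  }
})

test_that("datasets round-trip through the on-disk text format", {
  spec <- synthetic_spec(n_cells = 2, n_shared_pos = 6, n_neg = 6, seed = 12)
  ds <- split_dataset(generate_dataset(spec), seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(ds2$sequence, ds$sequence)
  expect_equal(ds2$labels, ds$labels)
  expect_equal(dataset_split(ds2), dataset_split(ds))
  expect_equal(ds2$histone[[3]], ds$histone[[3]], tolerance = 1e-10)
})

test_that("FASTA/BED/bedGraph exports are readable by the standard parsers", {
  spec <- synthetic_spec(n_cells = 2, n_shared_pos = 6, n_neg = 4, seed = 13)
  ds <- generate_dataset(spec)
  dir <- withr::local_tempdir()
  fa <- export_fasta(ds, file.path(dir, "seq.fasta"))
  seqs <- read_genome(fa)
  expect_equal(unname(seqs[ds$id]), ds$sequence)
  beds <- export_bed(ds, file.path(dir, "peaks"))
  p1 <- read_peaks(beds[1])
  pos1 <- ds[vapply(ds$labels, function(l) l[["cell1"]] == 1L, TRUE), ]
  expect_equal(p1$start, pos1$start)
  expect_equal(p1$end, pos1$end)
  bgs <- export_bedgraph(ds, file.path(dir, "tracks"))
  cov <- read_coverage_track(bgs[1])
  mark1 <- histone_marks()[1]
  i <- 2 # windows are laid out without overlap, so slices recover exactly
  got <- tfgate:::slice_coverage(cov$syn, ds$start[i], ds$end[i])
  expect_equal(got, unname(ds$histone[[i]][mark1, ]), tolerance = 1e-6)
})
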