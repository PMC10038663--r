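pwm_from_consensus <- function(consensus, id = "M1", tf = "TFX") {
  cons <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, 4, length(cons),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(cons, c("A", "C", "G", "T")), seq_along(cons))] <- 97
  new_pwm(id, tf, counts)
}

# non-palindromic strong consensus, so +/- hits stay distinct
simple_pwm <- function() pwm_from_consensus("TGCAGTCA")

test_that("pwm construction, pseudocount frequencies and consensus", {
  counts <- matrix(c(10, 0, 0, 0), 4, 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- new_pwm("m", "tf", counts)
  pr <- pwm_probs(p)
  expect_equal(unname(pr[1, 1]), (10 + 0.1 * 0.25) / 10.1)
  expect_equal(unname(pr[2, 1]), (0 + 0.1 * 0.25) / 10.1)
  expect_equal(colSums(pr), rep(1, 4))
  expect_equal(pwm_consensus(p), "AAAA")
  expect_error(new_pwm("m", "tf", counts[1:3, ]), "4 rows")
  expect_error(new_pwm("m", "tf", counts[, 1:3]), ">= 4")
})

test_that("log_odds_score: maximality, uniform zero, summation oracle", {
  p <- simple_pwm()
  expect_equal(log_odds_score(p, pwm_consensus(p)), pwm_max_score(p))
  # any other kmer scores strictly less
  expect_lt(log_odds_score(p, "TGCAGTCC"), pwm_max_score(p))
  # uniform PWM scores 0 for any kmer
  u <- new_pwm("u", "u", matrix(25, 4, 6,
                                dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(log_odds_score(u, "ACGTAC"), 0)
  # N contributes 0
  expect_equal(log_odds_score(u, "ACGNAC"), 0)
  expect_error(log_odds_score(p, "ACGT"), "length")
  # random pairs against an explicit per-position summation
  set.seed(31)
  for (i in 1:20) {
    rp <- random_pwm(7)
    kmer <- random_seq(7)
    lo <- log2(pwm_probs(rp) / rp$background)
    idx <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
    expect_equal(log_odds_score(rp, kmer), sum(lo[cbind(idx, 1:7)]))
  }
})

test_that("plant_motif substitutes the strand-adjusted consensus", {
  # the classic palindromic octamer: prefix replaced verbatim
  ap1 <- pwm_from_consensus("TGACGTCA", id = "AP1", tf = "AP1")
  s <- paste(rep("A", 20), collapse = "")
  expect_equal(substr(plant_motif(s, ap1, 0, "+"), 1, 8), "TGACGTCA")
  # non-palindrome on the minus strand: the reverse complement appears
  p <- simple_pwm()
  expect_equal(substr(plant_motif(s, p, 5, "-"), 6, 13),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("TGCAGTCA"))))
  expect_error(plant_motif(s, p, 15, "+"), "out of range")
  # planted window scores the PWM maximum
  planted <- plant_motif(s, p, 4, "+")
  expect_equal(log_odds_score(p, substr(planted, 5, 12)), pwm_max_score(p))
})

test_that("scan_site finds planted instances and respects the threshold", {
  p <- simple_pwm()
  set.seed(41)
  s <- plant_motif(random_seq(60), p, 23, "+")
  hits <- scan_site(s, p, threshold = 10)
  expect_true(any(hits$offset == 23 & hits$strand == "+"))
  expect_equal(hits$matched_seq[hits$offset == 23 & hits$strand == "+"],
               "TGCAGTCA")
  # minus strand plant maps back to forward offsets
  s2 <- plant_motif(random_seq(60), p, 40, "-")
  h2 <- scan_site(s2, p, threshold = 10)
  expect_true(any(h2$offset == 40 & h2$strand == "-"))
  # short sequence -> empty
  expect_equal(nrow(scan_site("ACGT", p)), 0)
  # raising the threshold never adds hits
  lo <- scan_site(s, p, threshold = 5)
  hi <- scan_site(s, p, threshold = 12)
  expect_true(all(paste(hi$offset, hi$strand) %in%
                    paste(lo$offset, lo$strand)))
})

test_that("scan_site strand symmetry on the reverse complement", {
  p <- simple_pwm()
  set.seed(43)
  s <- plant_motif(plant_motif(random_seq(80), p, 10, "+"), p, 50, "-")
  h <- scan_site(s, p, threshold = 10)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h2 <- scan_site(rc, p, threshold = 10)
  n <- nchar(s); L <- ncol(p$counts)
  mirrored <- data.frame(offset = n - L - h$offset,
                         strand = ifelse(h$strand == "+", "-", "+"),
                         score = h$score)
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  expect_equal(h2$offset, mirrored$offset)
  expect_equal(h2$strand, mirrored$strand)
  expect_equal(h2$score, mirrored$score)
})

test_that("scan_site equals the exhaustive window oracle", {
  set.seed(47)
  for (i in 1:12) {
    pw <- random_pwm(sample(6:9, 1), peaked = TRUE)
    s <- random_seq(sample(100:300, 1))
    thr <- sample(c(4, 8, 10), 1)
    got <- scan_site(s, pw, threshold = thr)
    want <- scan_oracle(s, pw, threshold = thr)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score)
  }
})

test_that("motif files round-trip through MEME and JASPAR parsers", {
  p <- simple_pwm()
  meme <- tempfile(fileext = ".meme")
  write_meme(list(p), meme)
  lib <- suppressMessages(load_motifs(meme))
  expect_equal(attr(lib, "n_loaded"), 1)
  expect_equal(pwm_consensus(lib[[1]]), "TGCAGTCA")
  expect_equal(lib[[1]]$tf, "TFX")

  jas <- tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 SOX2::POU5F1",
               "A [ 10  0  2  0 ]", "C [  0  1  1  9 ]",
               "G [  0  9  1  1 ]", "T [  0  0  6  0 ]"), jas)
  lib2 <- suppressMessages(load_motifs(jas))
  expect_equal(lib2[[1]]$motif_id, "MA0001.1")
  expect_equal(lib2[[1]]$tfs, c("SOX2", "POU5F1"))  # dimer maps to both
  expect_equal(unname(lib2[[1]]$counts[, 1]), c(10, 0, 0, 0))

  # unmapped TF kept with warning
  expect_warning(suppressMessages(load_motifs(meme, gene_ids = c("SOX2"))),
                 "M1")
  # 91-file library reports 91 motifs (count contract)
  dir91 <- tempfile(); dir.create(dir91)
  set.seed(53)
  files <- vapply(1:91, function(i) {
    f <- file.path(dir91, sprintf("m%02d.meme", i))
    write_meme(list(new_pwm(sprintf("M%02d", i), sprintf("TF%02d", i),
                            matrix(sample(1:20, 24, TRUE), 4, 6,
                                   dimnames = list(c("A", "C", "G", "T"),
                                                   NULL)))), f)
    f
  }, character(1))
  expect_message(lib91 <- load_motifs(files), "91 motif")
  expect_equal(attr(lib91, "n_loaded"), 91)
})

test_that("hits_for_gene maps TFs, dedupes, and skips unmapped motifs", {
  p <- simple_pwm()
  decoy <- new_pwm("D1", "NOTAGENE", p$counts)
  set.seed(59)
  seq1 <- plant_motif(plant_motif(random_seq(80), p, 5, "+"), p, 40, "+")
  sites <- data.frame(site_id = c("s1", "s2"), chrom = "chr1",
                      start = c(1000L, 2000L), end = c(1080L, 2080L))
  seqs <- Biostrings::DNAStringSet(c(seq1, random_seq(80)))
  h <- hits_for_gene(sites, seqs, list(p, decoy), grn_genes = c("TFX"))
  # two identical plants at different offsets -> two rows; site2 absent
  expect_equal(sum(h$site_id == "s1" & h$offset %in% c(5, 40)), 2)
  expect_false("s2" %in% h$site_id)
  expect_false("NOTAGENE" %in% h$tf_gene)
  # genomic coordinates derive from site start + offset
  expect_equal(sort(h$genomic_start[h$offset %in% c(5, 40)]),
               c(1005L, 1040L))
})
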