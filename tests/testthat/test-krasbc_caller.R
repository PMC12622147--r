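test_that("anchored trimming recovers payloads under substitution errors", {
  a5 <- "CTCTATCGTAGGGTCATA"
  a3 <- "CATTTTCAGCAGGCCT"
  x <- "ACGTACGTACGTACGTACGT"
  expect_identical(trim_krasbc(paste0(a5, x, a3)), x)
  # 3 substitutions in the 18-nt 5' anchor (rate 3/18 <= 0.2) still match
  a5_mut <- a5
  substr(a5_mut, 1, 1) <- "T"; substr(a5_mut, 9, 9) <- "C"
  substr(a5_mut, 18, 18) <- "C"
  expect_identical(trim_krasbc(paste0(a5_mut, x, a3)), x)
  # 4 substitutions exceed the tolerance: read dropped
  substr(a5_mut, 5, 5) <- "C"
  expect_identical(trim_krasbc(paste0(a5_mut, x, a3)), NA_character_)
  # no 5' anchor at all
  expect_identical(trim_krasbc(strrep("A", 60)), NA_character_)
  # 3' anchor optional
  expect_identical(trim_krasbc(paste0(a5, x)), x)
  # empty payload after trimming is a drop
  expect_identical(trim_krasbc(paste0(a5, a3)), NA_character_)
})

test_that("trimming equals the error-tolerant alignment oracle on fuzzed reads", {
  a5 <- "CTCTATCGTAGGGTCATA"
  a3 <- "CATTTTCAGCAGGCCT"
  set.seed(101)
  reads <- vapply(1:200, function(i) {
    pay <- clonotrace:::random_dna(1, sample(10:60, 1))
    lead <- clonotrace:::random_dna(1, sample(0:5, 1))
    r <- if (runif(1) < 0.8) {
      paste0(lead, a5, pay, if (runif(1) < 0.7) a3 else "")
    } else {
      clonotrace:::random_dna(1, 80)  # no adapter planted
    }
    clonotrace:::add_substitution_errors(r, 0.03)
  }, "")
  expect_identical(trim_krasbc(reads), oracle_trim(reads, a5, a3))
})

test_that("allele assignment applies distance, margin and ambiguity rules", {
  al <- small_alleles(n = 4)
  ref <- c(setNames(al$coding_sequence, al$barcode_id),
           Kras_WT = kras_wildtype_sequence())
  expect_identical(assign_allele(kras_wildtype_sequence(), ref), "Kras_WT")
  # one substitution outside variable positions still assigns
  p <- al$coding_sequence[2]
  substr(p, 45, 45) <- if (substr(p, 45, 45) == "A") "C" else "A"
  expect_identical(assign_allele(p, ref), al$barcode_id[2])
  # payload equidistant between two references is unassigned
  two <- c(A = strrep("A", 20), B = strrep("C", 20))
  mid <- paste0(strrep("A", 10), strrep("C", 10))
  expect_identical(assign_allele(mid, two, max_mismatch_rate = 0.6),
                   NA_character_)
  # NA and empty payloads are unassigned
  expect_identical(assign_allele(c(NA, ""), ref), c(NA_character_, NA_character_))
  # distance beyond ceiling(rate * len) is unassigned
  far <- clonotrace:::add_substitution_errors(al$coding_sequence[1], 0.4)
  expect_identical(assign_allele(far, ref, max_mismatch_rate = 0.05),
                   NA_character_)
})

test_that("UMI collapse counts one transcript per cell/allele/UMI triple", {
  x <- data.frame(
    cell_barcode = rep("CELL1", 7),
    umi = c(rep("UUUUUUUUUU", 5), "UUUUUUUUUU", "VVVVVVVVVV"),
    allele = c(rep("BC1", 5), "Kras_WT", "BC1"),
    stringsAsFactors = FALSE)
  got <- collapse_umis(x)
  expect_equal(got$umis[got$allele == "BC1"], 2L)       # 5 dups -> 1, + V
  expect_equal(got$umis[got$allele == "Kras_WT"], 1L)   # same UMI, own allele
  empty <- collapse_umis(x[0, ])
  expect_equal(nrow(empty), 0L)
  # unassigned reads are ignored
  x$allele[1:5] <- NA
  got2 <- collapse_umis(x)
  expect_equal(sum(got2$umis), 2L)
})

test_that("barcode merging absorbs near neighbours and conserves UMIs", {
  expect_equal(merge_barcodes(c(AAAA = 10, AAAT = 1)), c(AAAA = 11))
  expect_equal(merge_barcodes(c(AAAA = 10, TTTT = 4)),
               c(AAAA = 10, TTTT = 4))
  # random toy sets match the brute-force oracle, and UMIs are conserved
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    ids <- unique(clonotrace:::random_dna(n, 6))
    counts <- setNames(sample(1:30, length(ids), replace = TRUE), ids)
    got <- merge_barcodes(counts)
    want <- oracle_merge(counts)
    expect_equal(got[order(names(got))], want[order(names(want))])
    expect_equal(sum(got), sum(counts))
  }
})

test_that("clonotype calling applies the somatic/excluded/malignant rules", {
  mk <- function(wt, bc = numeric(0), tu = 1000, ds = 1000) {
    cell_allele_counts("CELLX", wt, bc, tu, ds)
  }
  expect_identical(call_clonotype(mk(3))$cell_class, "somatic")
  expect_identical(call_clonotype(mk(2))$cell_class, "somatic")
  expect_identical(call_clonotype(mk(1))$cell_class, "excluded")
  expect_identical(call_clonotype(mk(0))$cell_class, "excluded")
  # pipeline trace: wt=1, {BC1:7, BC2:1} merges (distance 1) then calls BC1
  merged <- merge_barcodes(c(BCA = 7, BCT = 1))
  call <- call_clonotype(mk(1, merged))
  expect_identical(call$cell_class, "malignant")
  expect_identical(call$dominant_barcode, "BCA")
  expect_equal(call$g12d_umis, 8)
  # tied dominant barcode excludes the cell
  tie <- call_clonotype(mk(1, c(AAAAAA = 5, TTTTTT = 5)))
  expect_identical(tie$cell_class, "excluded")
  expect_identical(tie$dominant_barcode, NA_character_)
  # zero transcriptome: excluded, abundance undefined
  z <- call_clonotype(mk(3, c(AAAAAA = 5), tu = 0))
  expect_identical(z$cell_class, "excluded")
  expect_true(is.na(z$kras_abundance))
  # abundance = (wt + sum bc) / transcriptome * depth_scale
  ab <- call_clonotype(mk(2, c(AAAAAA = 8), tu = 2000, ds = 1000))
  expect_equal(ab$kras_abundance, (2 + 8) / 2000 * 1000)
})

test_that("imbalance classification follows the threshold rules", {
  mk_call <- function(g12d, wt) {
    counts <- cell_allele_counts("C", wt, c(BC1 = g12d), 1000, 1000)
    list(call = call_clonotype(counts), counts = counts)
  }
  x <- mk_call(10, 0)
  expect_identical(classify_imbalance(x$call, x$counts), "g12d_high")
  x <- mk_call(5, 5)
  expect_identical(classify_imbalance(x$call, x$counts), "balanced")
  x <- mk_call(1, 9)
  expect_identical(classify_imbalance(x$call, x$counts), "wt_high")
  x <- mk_call(2, 1)
  expect_identical(classify_imbalance(x$call, x$counts), "indeterminate")
  x <- mk_call(3, 1)  # t = 4, fraction 0.75 inclusive
  expect_identical(classify_imbalance(x$call, x$counts), "g12d_high")
  somatic <- call_clonotype(cell_allele_counts("C", 5, numeric(0), 1000, 1000))
  expect_error(classify_imbalance(somatic,
                                  cell_allele_counts("C", 5, numeric(0), 1000, 1000)),
               "malignant")
})

test_that("imbalance labels are recovered from simulated depth-20 cells", {
  # Independent closed-form oracle for the expected label accuracy under the
  # stated generative model (beta-binomial balanced cells, uniform [0.75, 1]
  # skewed cells, negative-binomial depth, threshold 0.75, min_total 4).
  # At mean depth 20 the binomial tails bound the attainable accuracy near
  # 93-95%; the classifier must match the oracle, not beat the noise floor.
  oracle_accuracy <- function(p_hi = 0.15, mu = 20, size = 10, a = 100,
                              thr = 0.75, min_total = 4, tmax = 80) {
    ts <- min_total:tmax
    wt_t <- dnbinom(ts, mu = mu, size = size)
    wt_t <- wt_t / sum(wt_t)
    fgrid <- seq(0.75, 1, length.out = 2001)
    acc_t <- vapply(ts, function(t) {
      x <- 0:t
      # beta-binomial mass for balanced cells
      bb <- choose(t, x) * beta(x + a, t - x + a) / beta(a, a)
      ok_bal <- (x / t < thr) & ((t - x) / t < thr)
      p_bal <- sum(bb[ok_bal])
      # uniform mixture of binomials for skewed cells
      p_hi_t <- mean(vapply(fgrid, function(f) {
        sum(dbinom(x[x / t >= thr], t, f))
      }, 0))
      (1 - p_hi) * p_bal + p_hi * p_hi_t
    }, 0)
    sum(wt_t * acc_t)
  }
  expected <- oracle_accuracy()
  al <- small_alleles()
  m <- tumor_model(n_cells = 3000, n_clones = 6, kras_mean_umis = 20,
                   p_somatic = 0, p_spikein = 0, seed = 17)
  truth <- simulate_tumor(m, al)
  state <- clonotrace:::imbalance_state_from_counts(truth$kras_g12d_umis,
                                                    truth$kras_wt_umis)
  det <- state != "indeterminate"
  acc <- mean(state[det] == truth$imbalance_state[det])
  expect_gte(acc, 0.9)
  expect_lt(abs(acc - expected), 0.015)  # ~3.5 sd of the empirical accuracy
})

test_that("adding reads never decreases UMI counts (monotonicity)", {
  set.seed(31)
  base <- data.frame(
    cell_barcode = sample(c("C1", "C2"), 40, TRUE),
    umi = clonotrace:::random_dna(40, 4),
    allele = sample(c("Kras_WT", "BC1", "BC2"), 40, TRUE),
    stringsAsFactors = FALSE)
  extra <- data.frame(cell_barcode = "C1",
                      umi = clonotrace:::random_dna(5, 4),
                      allele = "BC1", stringsAsFactors = FALSE)
  a <- collapse_umis(base)
  b <- collapse_umis(rbind(base, extra))
  key <- function(d) setNames(d$umis, paste(d$cell_barcode, d$allele))
  ka <- key(a); kb <- key(b)
  expect_true(all(kb[names(ka)] >= ka))
})

test_that("cell classes partition all cells exhaustively", {
  al <- small_alleles()
  truth <- simulate_tumor(tumor_model(n_cells = 300, n_clones = 5, seed = 23), al)
  counts <- data.frame(
    cell_barcode = rep(truth$cell_barcode, 2),
    allele = c(ifelse(is.na(truth$clone_barcode_id), "Kras_WT",
                      truth$clone_barcode_id), rep("Kras_WT", nrow(truth))),
    umis = c(truth$kras_g12d_umis, truth$kras_wt_umis),
    stringsAsFactors = FALSE)
  counts <- counts[counts$umis > 0, ]
  counts$allele[is.na(counts$allele)] <- "Kras_WT"
  calls <- call_clonotypes(counts,
                           truth[, c("cell_barcode", "transcriptome_umis")])
  expect_equal(nrow(calls), nrow(truth))
  expect_true(all(calls$cell_class %in% c("malignant", "somatic", "excluded")))
  expect_true(all(is.na(calls$dominant_barcode[calls$cell_class == "somatic"])))
  expect_true(all(!is.na(calls$dominant_barcode[calls$cell_class == "malignant"])))
})
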