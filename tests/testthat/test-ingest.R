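write_tsv_features <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_features <- function(rows) {
  data.frame(sample_id = "toy", raw_name = rows$name, start = rows$start,
             end = rows$end, strand = rows$strand,
             feature_class = rows$class,
             anticodon = if (is.null(rows$anticodon)) NA_character_
                         else rows$anticodon,
             stringsAsFactors = FALSE)
}

test_that("TSV features parse with coordinates, strand and wrap flags", {
  df <- toy_features(list(name = c("ND1", "tRNA-Phe", "D-loop"),
                          start = c(100, 1200, 16500),
                          end = c(1050, 1270, 300),
                          strand = c("+", "-", "+"),
                          class = c("gene", "tRNA", "D-loop")))
  f <- parse_features(write_tsv_features(df), "tsv")
  expect_equal(nrow(f), 3L)
  expect_identical(f$strand, c(1L, -1L, 1L))
  expect_true(f$wrap[3])                      # spans the circular origin
  expect_equal(f$length[1], 951L)
  bad <- df; bad$strand[2] <- "?"
  expect_error(parse_features(write_tsv_features(bad), "tsv"),
               "bad strand in data row 2")
})

test_that("wrapping feature length is computed modulo the genome", {
  # toy record: genome of 1000 bp, feature 950..1000 joined with 1..50
  f <- data.frame(sample_id = "toy", raw_name = "CR", start = 950L,
                  end = 50L, strand = 1L, feature_class = "D-loop",
                  anticodon = NA_character_, wrap = TRUE, length = NA)
  f$length <- 1000L - f$start + 1L + f$end
  expect_equal(f$length, 101L)
})

test_that("the packaged GenBank fixture yields the vertebrate order", {
  gb <- system.file("extdata", "synthetic_mitogenome.gb", package = "mgorder")
  f <- parse_features(gb, "genbank")
  expect_equal(nrow(f), 39L)
  expect_true("D-loop" %in% f$feature_class)
  gl <- attr(f, "genome_length")[["SYN0001"]]
  res <- order_from_features(f, gl)
  expect_identical(format(res$order), format(vertebrate_order()))
  expect_length(res$flags, 0L)
})

test_that("gene-name synonyms map onto the controlled vocabulary", {
  expect_identical(standardize_names("ND5", "gene")$token, "nad5")
  expect_identical(standardize_names("NADH dehydrogenase subunit 4L",
                                     "gene")$token, "nad4l")
  expect_identical(standardize_names("COI", "gene")$token, "cox1")
  expect_identical(standardize_names("12S rRNA", "rRNA")$token, "rrnS")
  expect_identical(standardize_names("anything", "D-loop")$token, "CR")
  expect_identical(standardize_names("tRNA-Phe", "tRNA")$token, "trnF")
  res <- standardize_names("some ORF", "gene")
  expect_identical(res$token, "extra")
  expect_identical(res$flag, "name-unrecognized")
})

test_that("leucine/serine tRNAs disambiguate by anticodon then position", {
  expect_identical(standardize_names("tRNA-Leu", "tRNA",
                                     anticodon = "UAG")$token, "trnL1")
  expect_identical(standardize_names("tRNA-Leu", "tRNA",
                                     anticodon = "taa")$token, "trnL2")
  expect_identical(standardize_names("tRNA-Ser", "tRNA",
                                     anticodon = "GCU")$token, "trnS1")
  # positional fallback: a leucine tRNA flanked by trnS1 and nad5 is trnL1
  expect_identical(standardize_names("tRNA-Leu", "tRNA",
                                     context = c("trnS1", "nad5"))$token,
                   "trnL1")
  expect_identical(standardize_names("tRNA-Leu", "tRNA",
                                     context = c("rrnL", "nad1"))$token,
                   "trnL2")
  res <- standardize_names("tRNA-Leu", "tRNA")
  expect_identical(res$flag, "leucine-serine-ambiguous")
})

test_that("control regions are detected from large intergenic gaps", {
  mk <- function(starts, ends) {
    toy_features(list(name = paste0("g", seq_along(starts)), start = starts,
                      end = ends, strand = rep("+", length(starts)),
                      class = rep("gene", length(starts))))
  }
  f <- parse_features(write_tsv_features(mk(c(1, 1000, 3000),
                                            c(900, 2050, 3500))), "tsv")
  out <- detect_control_regions(f, 3600, min_gap = 250)
  crs <- out[out$feature_class == "D-loop", ]
  expect_equal(nrow(crs), 1L)                  # the 949 bp gap at 2051..2999
  expect_equal(crs$start, 2051L)
  expect_equal(crs$length, 949L)
  # no gap reaches the threshold
  f2 <- parse_features(write_tsv_features(mk(c(1, 1000), c(900, 2000))), "tsv")
  expect_equal(sum(detect_control_regions(f2, 2100,
                                          min_gap = 250)$feature_class ==
                     "D-loop"), 0L)
  # two gaps, as in the Caudata pattern (extra CR between trnT and trnP)
  f3 <- parse_features(write_tsv_features(mk(c(1, 1500, 3000),
                                             c(900, 2000, 3100))), "tsv")
  out3 <- detect_control_regions(f3, 4400, min_gap = 250)
  expect_equal(sum(out3$feature_class == "D-loop"), 3L)  # 2 internal + wrap
})

test_that("raising the gap threshold never adds a control region", {
  set.seed(66)
  for (rep in 1:10) {
    n <- 8
    starts <- cumsum(c(1, sample(50:800, n - 1, TRUE)))
    ends <- starts + sample(60:200, n, TRUE)
    df <- toy_features(list(name = paste0("g", 1:n), start = starts,
                            end = ends, strand = rep("+", n),
                            class = rep("gene", n)))
    f <- parse_features(write_tsv_features(df), "tsv")
    gl <- max(ends) + sample(0:600, 1)
    counts <- vapply(c(100, 250, 400, 800), function(th) {
      sum(detect_control_regions(f, gl, min_gap = th)$feature_class ==
            "D-loop")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("validation reproduces the canonical error taxonomy", {
  v <- vertebrate_order()
  # trnY annotated on the wrong strand, everything else intact
  toks <- mgorder:::format_tokens(v)
  toks[toks == "-trnY"] <- "trnY"
  r1 <- validate_order(canonicalize(gene_order(toks, sample_id = "s1")))
  expect_identical(r1$issues$flag, "abnormal-strand")
  expect_identical(r1$issues$detail, "trnY")
  expect_true(r1$usable)
  # a missing trnM
  r2 <- validate_order(canonicalize(
    gene_order(toks[!toks %in% "trnM"], sample_id = "s2")))
  expect_true("missing-gene" %in% r2$issues$flag)
  expect_false(r2$usable)
  # intact order: clean report
  r3 <- validate_order(v)
  expect_equal(nrow(r3$issues), 0L)
  expect_true(r3$usable)
  # duplications are recorded but not fatal
  r4 <- validate_order(caudata_order())
  expect_identical(r4$issues$flag, "duplicate-unexpected")
  expect_true(r4$usable)
})

test_that("simulated loss-free genomes validate without missing genes", {
  cfg <- sim_config(n_families = 3, tips_per_family = c(2, 3),
                    rates = c(translocation = 4e-3, inversion = 4e-4,
                              duplication = 1e-3, cr_duplication = 2e-3,
                              loss = 0), seed = 77)
  sim <- simulate_events(simulate_tree(cfg), cfg)
  for (o in sim$tip_orders) {
    expect_false("missing-gene" %in% validate_order(o)$issues$flag)
  }
})
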