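test_that("base calling applies depth bounds and strict majority", {
  cnt <- rbind(c(9, 0, 1, 0),    # depth 10, A 90%
               c(5, 0, 3, 0),    # depth 8, A 62.5%
               c(2, 0, 0, 0),    # depth 2
               c(30, 0, 0, 0),   # depth 30
               c(6, 2, 0, 0))    # depth 8, A exactly 75%
  cc <- call_bases(cnt)
  expect_equal(cc$base, c("A", NA, NA, NA, NA))
  expect_equal(cc$reason,
               c(NA, "no_majority", "low_depth", "high_depth",
                 "no_majority"))
  ## a designated high-coverage line may allow depth 30
  cc40 <- call_bases(cnt, max_depth = 40)
  expect_equal(cc40$base[4], "A")
  expect_error(call_bases(rbind(c(-1, 0, 0, 0))), "negative")
})

test_that("the SNP table keeps only sites callable in all lines and polymorphic", {
  lines <- sprintf("line%02d", 0:9)
  mk <- function(bases) {
    lapply(seq_along(lines), function(i) {
      data.frame(chrom = "chr1", pos = seq_along(bases[[1]]) * 100L,
                 base = bases[[i]], stringsAsFactors = FALSE)
    }) |> setNames(lines)
  }
  ## site 1: 7 A / 3 G; site 2: one line missing; site 3: monomorphic
  bases <- lapply(1:10, function(i) {
    c(ifelse(i <= 7, "A", "G"),
      ifelse(i == 4, NA, "C"),
      "T")
  })
  tab <- build_snp_table(mk(bases))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$pos, 100L)
  expect_equal(tab$maf, 0.3)
  expect_equal(tab$major, "A")
  expect_equal(tab$minor, "G")
  expect_false(tab$multiallelic)
})

test_that("coding-effect annotation matches the genetic code by strand", {
  ## gene on +: exon covering codons GGA GAA TGC at positions 100..108
  ref <- Biostrings::DNAString(paste(c(
    paste(rep("T", 100), collapse = ""), "GGAGAATGC",
    paste(rep("T", 100), collapse = "")), collapse = ""))
  feats <- data.frame(
    chrom = "chr1", start = c(90L, 100L), end = c(120L, 109L),
    kind = c("gene", "exon"), family = NA,
    transcript_id = c(NA, "tx1"), gene_id = "g1",
    strand = "+", longest = c(NA, TRUE), stringsAsFactors = FALSE)
  snps <- data.frame(chrom = "chr1", pos = c(102L, 104L, 95L),
                     major = c("A", "A", "T"), minor = c("G", "A", "C"))
  ## GGA -> GGG (Gly/Gly): synonymous at codon position 3
  snps$minor[1] <- "G"; snps$major[1] <- "A"
  ## GAA -> GGA (Glu -> Gly): nonsynonymous
  snps$major[2] <- "A"; snps$minor[2] <- "G"
  eff <- annotate_effect(snps, feats, ref)
  expect_equal(eff, c("synonymous", "nonsynonymous", "noncoding"))

  ## frame not a multiple of 3 -> warning, sites skipped
  feats2 <- feats
  feats2$end[2] <- 108L
  expect_warning(annotate_effect(snps, feats2, ref), "multiple of 3")
})

test_that("effect annotation agrees with whole-CDS translation on random genes", {
  set.seed(7)
  code <- Biostrings::GENETIC_CODE
  for (rep in 1:25) {
    n_codons <- sample(5:20, 1)
    cds <- paste(sample(c("A", "C", "G", "T"), n_codons * 3, TRUE),
                 collapse = "")
    lead <- paste(rep("A", 50), collapse = "")
    strand <- sample(c("+", "-"), 1)
    genomic <- if (strand == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    ref <- Biostrings::DNAString(paste0(lead, genomic, lead))
    feats <- data.frame(chrom = "chr1", start = c(45L, 50L),
                        end = c(55L + n_codons * 3L, 50L + n_codons * 3L),
                        kind = c("gene", "exon"), family = NA,
                        transcript_id = c(NA, "tx"), gene_id = "g",
                        strand = strand, longest = c(NA, TRUE),
                        stringsAsFactors = FALSE)
    pos <- sample(50:(50 + n_codons * 3 - 1), 1)
    refb <- substr(as.character(ref), pos + 1, pos + 1)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    snp <- data.frame(chrom = "chr1", pos = pos, major = refb, minor = altb)
    eff <- annotate_effect(snp, feats, ref)
    ## oracle: translate the whole mutant CDS
    mutg <- as.character(ref)
    substr(mutg, pos + 1, pos + 1) <- altb
    take <- function(s) substr(s, 51, 50 + n_codons * 3)
    tr <- function(s) {
      s <- Biostrings::DNAString(s)
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(Biostrings::translate(s, no.init.codon = TRUE))
    }
    expected <- if (tr(take(as.character(ref))) == tr(take(mutg)))
      "synonymous" else "nonsynonymous"
    expect_equal(eff, expected,
                 info = sprintf("rep %d strand %s pos %d", rep, strand, pos))
  }
})

test_that("planted SNPs eligible in all lines are recovered exactly", {
  cfg <- sim_config(seed = 81, genome_length = 3e5, n_genes = 20, n_tes = 40,
                    deletion_count = 4, deletion_size_range = c(1000, 20000),
                    snp_density = 0.005, repeat_hotspot_count = 0)
  truth <- generate_truth(cfg)
  pile <- simulate_pileups(truth, cfg)
  calls <- lapply(pile, function(p) {
    cbind(p[, c("chrom", "pos")], call_bases(p[, c("A", "C", "G", "T")]))
  })
  tab <- build_snp_table(calls[truth$focal_lines],
                         focal_lines = truth$focal_lines)
  ## recovered = planted sites where every line had usable depth
  eligible <- truth$snps$pos[vapply(seq_len(nrow(truth$snps)), function(i) {
    all(vapply(truth$focal_lines, function(acc) {
      d <- calls[[acc]]$depth[i]
      d >= 3 && d <= 25
    }, logical(1)))
  }, logical(1))]
  expect_setequal(tab$pos, eligible)
  ## allele counts match the planted carrier sets
  m <- match(tab$pos, truth$snps$pos)
  expect_equal(tab$minor_count, truth$snps$m[m])
})
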