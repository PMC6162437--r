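test_that("identical sequences align gap-free with an identity map", {
  tp <- generate_toy_protein_pair(80, seed = 1)
  al <- align_proteins(tp$a, tp$a)
  expect_false(grepl("-", al$aligned_a, fixed = TRUE))
  expect_identical(al$map_ab, 1:80)
  expect_identical(map_residue(al, 37), 37L)
  # self-alignment scores at least as high as against a mutated copy
  tpm <- generate_toy_protein_pair(80, n_substitutions = 20, seed = 1)
  expect_gte(al$score, align_proteins(tpm$a, tpm$b)$score)
})

test_that("alignment recovers constructed insertion offsets", {
  # an N-terminal 13-residue insertion: the canine-162 -> human-175 situation
  tp <- generate_toy_protein_pair(250, insertions = list(c(1, 13)),
                                  n_substitutions = 8, seed = 2)
  al <- align_proteins(tp$a, tp$b)
  for (p in c(1, 50, 162, 250))
    expect_identical(map_residue(al, p), tp$map[[p]])
  # internal insertion: positions below the breakpoint map identically
  tp2 <- generate_toy_protein_pair(120, insertions = list(c(50, 5)), seed = 3)
  al2 <- align_proteins(tp2$a, tp2$b)
  expect_identical(map_residue(al2, 20), 20L)
  expect_identical(map_residue(al2, 80), 85L)
  # correspondence is monotone and injective on mapped positions
  mp <- al2$map_ab[!is.na(al2$map_ab)]
  expect_true(all(diff(mp) > 0))
})

test_that("synthetic TP53-like pair maps 162->175 and 261->273", {
  # synthetic stand-in for the dog/human TP53 pair: a 13-residue N-terminal
  # extension plus one deleted residue between the two hotspots gives the
  # +13 / +12 offsets of the two known hotspot equivalences
  set.seed(4)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  dog <- paste(sample(aa, 320, replace = TRUE), collapse = "")
  human <- paste0(paste(sample(aa, 13, replace = TRUE), collapse = ""),
                  substr(dog, 1, 199), substr(dog, 201, 320))
  al <- align_proteins(dog, human)
  expect_identical(map_residue(al, 162), 175L)
  expect_identical(map_residue(al, 261), 273L)
  expect_identical(map_residue(al, 200), "gapped")
  # mirror alignment gives the reverse correspondence
  al_rev <- align_proteins(human, dog)
  expect_identical(map_residue(al_rev, 175), 162L)
})

test_that("alignment input validation names the offending position", {
  expect_error(align_proteins("ACDX", "ACD"), "position 4")
  expect_error(align_proteins("", "ACD"), "non-empty")
  expect_error(map_residue(align_proteins("ACDE", "ACDE"), 9), "exceeds")
})

test_that("beta-catenin degron mutations flag by position and role", {
  expect_identical(flag_degron_mutation("CTNNB1", 45, "S", "P")$status,
                   "degron-disrupting")
  expect_identical(flag_degron_mutation("CTNNB1", 45, "S", "F")$role,
                   "priming-phospho")
  expect_identical(flag_degron_mutation("CTNNB1", 32, "D", "Y")$role,
                   "motif-structural")
  expect_identical(flag_degron_mutation("CTNNB1", 34, "G", "E")$role,
                   "motif-structural")
  expect_identical(flag_degron_mutation("CTNNB1", 60, "T", "S")$status,
                   "outside")
  expect_identical(flag_degron_mutation("CTNNB1", 38, "I", "V")$status,
                   "motif-adjacent")
  expect_error(flag_degron_mutation("TP53", 45, "S", "F"), "does not match")
  expect_error(flag_degron_mutation("CTNNB1", 45, "S", "S"), "must differ")
})

test_that("premature stops are found in the right frame with a scan oracle", {
  # exon (no in-frame stop) + retained intron carrying TAA and TAG + exon
  cds <- paste0("ATGGCCGCA", "TAAGTTTAGCCG", "TGA")
  res <- detect_premature_stops(cds, 0)
  # brute-force triplet scan oracle
  chars <- strsplit(cds, "")[[1]]
  starts <- seq(1, nchar(cds) - 2, by = 3)
  trip <- vapply(starts, function(s) paste(chars[s:(s + 2)], collapse = ""), "")
  oracle <- starts[trip %in% c("TAA", "TAG", "TGA")]
  oracle <- as.integer(oracle[oracle < max(oracle)])  # terminal stop excluded
  expect_identical(res$positions, oracle)
  expect_identical(length(res$positions), 2L)
  expect_identical(res$truncation_codons, as.integer((res$positions[1] - 1) / 3))
  # no in-frame stop in the intron
  expect_identical(detect_premature_stops("ATGAAACCCGGG", 0)$positions, integer())
  # shifting the frame changes which triplets are codons
  for (off in 0:2) {
    r <- detect_premature_stops(cds, off)
    st <- seq(1 + off, nchar(cds) - 2, by = 3)
    tr <- vapply(st, function(s) paste(chars[s:(s + 2)], collapse = ""), "")
    sp <- st[tr %in% c("TAA", "TAG", "TGA")]
    can <- if (length(sp) && sp[length(sp)] == st[length(st)])
      st[length(st)] else st[length(st)] + 3
    expect_identical(r$positions, as.integer(sp[sp < can]))
  }
  expect_error(detect_premature_stops("ATGN", 0), "invalid nucleotide")
})

test_that("protein FASTA round-trips through the reader", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">dogTP53 some description", "MEEPQSDPSV", ">humanTP53",
               "MEESQSDISL"), f)
  seqs <- read_protein_fasta(f)
  expect_identical(names(seqs), c("dogTP53", "humanTP53"))
  expect_identical(unname(seqs[["dogTP53"]]), "MEEPQSDPSV")
})
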