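test_that("reads failing length or primer checks are rejected with reasons", {
  scheme <- demo_scheme()
  insert <- paste(rep("ACGT", 75), collapse = "")
  good <- make_read(scheme, "S1", insert)            # Y->C, M->A in 8F
  short <- substr(good, 1, 90)
  no_rev <- paste0(substr(good, 1, 8 + 20 + 50),
                   strrep("A", nchar(good) - 8 - 20 - 50))
  res <- filter_reads(amplicon_reads(c("a", "b", "c"), c(good, short, no_rev)),
                      scheme)
  expect_equal(unname(res$log[c("kept", "length", "primer")]), c(1L, 1L, 1L))
  expect_equal(res$reason, c("kept", "length", "primer"))
  # IUPAC degeneracy: the other expansion of Y/M is also accepted
  alt <- make_read(scheme, "S1", insert, fwd = "AGAGTTTGATTCTGGCTCAG")
  expect_equal(filter_reads(amplicon_reads("d", alt), scheme)$log[["kept"]], 1L)
})

test_that("demultiplexing assigns on exact dual-tag matches and trims", {
  scheme <- demo_scheme()
  ins <- c("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
           "TTTTGGGGCCCCAAAATTTTGGGGCCCCAAAATTTTGGGGCCCCAAAATTTTGGGGCCCCAAAA")
  r1 <- make_read(scheme, "S1", ins[1])
  r2 <- make_read(scheme, "S2", ins[2])
  # conflict: S1's 5' tag with S2's 3' tag
  t5 <- scheme$tags$tag5[1]
  conflict <- paste0(t5, substr(r2, 9, nchar(r2)))
  dm <- demultiplex(amplicon_reads(c("r1", "r2", "rc"), c(r1, r2, conflict)),
                    scheme)
  expect_equal(dm$samples$S1$seq, ins[1])
  expect_equal(dm$samples$S2$seq, ins[2])
  expect_equal(dm$unassigned, 1L)
  # partition property: kept = assigned + unassigned; plus rejected = input
  expect_equal(dm$log[["kept"]], dm$log[["assigned"]] + dm$log[["unassigned"]])

  # trimming idempotence: already-trimmed reads carry no tags
  dm2 <- demultiplex(dm$samples$S1, scheme, filter = FALSE)
  expect_equal(dm2$log[["assigned"]], 0L)

  # reverse-complement consistency
  dmr <- demultiplex(amplicon_reads(c("r1", "r2"), revcomp_chr(c(r1, r2))),
                     scheme, orientation = "reverse")
  expect_equal(dmr$samples$S1$seq, ins[1])
  expect_equal(dmr$samples$S2$seq, ins[2])
})

test_that("error-free multiplexed reads demultiplex 100% to the right samples", {
  cfg <- sim_config(n_participants = 2, oral_pool_size = 10, gut_pool_size = 12,
                    shared_pool_size = 3, depth_tongue_mean = 250,
                    depth_tongue_sd = 10, depth_rectal_mean = 250,
                    depth_rectal_sd = 10, min_depth = 200,
                    sequences = TRUE, seq_length = 120, seed = 11)
  co <- generate_cohort(cfg)
  ids <- rownames(co$table)
  bases <- c("A", "C", "G", "T")
  set.seed(5)
  tags <- data.frame(sample_id = ids,
                     tag5 = replicate(length(ids), paste(sample(bases, 8, TRUE), collapse = "")),
                     tag3 = replicate(length(ids), paste(sample(bases, 8, TRUE), collapse = "")),
                     stringsAsFactors = FALSE)
  scheme <- tag_scheme(tags, "AGAGTTTGATYMTGGCTCAG", "TGCTGCCTCCCGTAGGAGT")
  fq <- generate_multiplexed_fastq(co$table, scheme, seed = 3)
  dm <- demultiplex(fq$reads, scheme)
  expect_equal(dm$log[["length"]] + dm$log[["primer"]], 0L)
  expect_equal(dm$unassigned, 0L)
  got <- vapply(ids, function(s) length(dm$samples[[s]]$seq), 0L)
  expect_equal(unname(got), as.integer(table(fq$truth$sample_id)[ids]))
  # insert lengths preserved
  expect_true(all(nchar(unlist(lapply(dm$samples, `[[`, "seq"))) == 120))

  # corrupted tags land exactly in unassigned
  fq2 <- generate_multiplexed_fastq(co$table, scheme, tag_error_fraction = 0.05,
                                    seed = 3)
  dm2 <- demultiplex(fq2$reads, scheme)
  expect_equal(dm2$unassigned, sum(fq2$truth$tag_corrupted))
  n_ok <- sum(!fq2$truth$tag_corrupted)
  expect_equal(dm2$log[["assigned"]], n_ok)

  # tabulated ASV counts match the simulated table
  tab <- tabulate_asvs(dm$samples)
  expect_equal(sort(unname(rowSums(tab))), sort(unname(rowSums(co$table))))
  expect_equal(sum(tab), sum(co$table))
})

test_that("fastq round-trips through files", {
  reads <- amplicon_reads(c("x", "y"), c("ACGTACGT", "GGGTTTCC"),
                          c("IIIIIIII", "ABCDEFGH"))
  tmp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
  expect_equal(back$id, reads$id)
})
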