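# Synthetic fixtures built in code: a toy genome, tiny peak/SNV tables and a
# minimal paired-end SAM file for the alignment-facing adapters.

# deterministic random genome with a few deliberate features
toy_genome <- function() {
  set.seed(401)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  # chrT: positions (0-based) 100-199 arbitrary; a homopolymer run AAAAA at
  # 150-154; a CT microsatellite-like stretch at 170-189
  left <- rand(150)
  chrT <- paste0(left, "AAAAA", rand(15), strrep("CT", 10), rand(810))
  c(chrT = chrT, chrU = rand(500))
}

uniform_random_genome <- function(n, seed = 402) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# long counts table for asb_test(): k replicates, x_ref/x_alt already normalised
make_counts_table <- function(x_ref, x_alt) {
  k <- ncol(x_ref)
  n <- nrow(x_ref)
  tibble::tibble(
    snv_id = rep(sprintf("s%03d", seq_len(n)), k),
    replicate = rep(paste0("rep", seq_len(k)), each = n),
    x_ref = as.vector(x_ref), x_alt = as.vector(x_alt))
}

# a variance trend with (nearly) constant CV2, for closed-form checks
constant_trend <- function(cv2 = 0.04) {
  mu <- seq(5, 500, length.out = 60)
  asbind::fit_variance_trend(mu, rep(cv2, 60))
}

# minimal coordinate-sorted SAM with paired reads on a 300 nt contig;
# returns the SAM path (convert with Rsamtools::asBam in the test)
write_toy_sam <- function(path) {
  ref <- "chrS"
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", sprintf("@SQ\tSN:%s\tLN:300", ref))
  sam_line <- function(qname, flag, pos, mapq, seq, qual) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t0\t%s\t%s",
            qname, flag, ref, pos, mapq, nchar(seq), pos, seq, qual)
  }
  q30 <- function(n) strrep("?", n)           # Phred 30
  q05 <- function(n) strrep("&", n)           # Phred 5
  lines <- c(
    # R1 mates (flag 99: paired, proper, mate reverse, first in pair) - skipped
    sam_line("frag1", 99, 41, 60, strrep("A", 20), q30(20)),
    # R2 forward (flag 163: paired, proper, mate reverse, second in pair)
    sam_line("frag2", 163, 51, 60, paste0(strrep("A", 10), "G", strrep("A", 9)), q30(20)),
    sam_line("frag3", 163, 51, 60, paste0(strrep("A", 10), "G", strrep("A", 9)), q30(20)),
    # same allele but low base quality at the SNV (pos 61 1-based)
    sam_line("frag4", 163, 51, 60, paste0(strrep("A", 10), "G", strrep("A", 9)), q05(20)),
    # R2 carrying the reference A at 61
    sam_line("frag5", 163, 51, 60, strrep("A", 20), q30(20)),
    # R2 reverse strand (flag 147)
    sam_line("frag6", 147, 51, 60, strrep("A", 20), q30(20)),
    # low MAPQ R2, must be dropped by the MAPQ filter
    sam_line("frag7", 163, 51, 3, strrep("A", 20), q30(20))
  )
  writeLines(c(hdr, lines), path)
  path
}

write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chrT\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "chrT\t201\t.\tC\tT\t.\tPASS\t.\tGT\t1/1",   # homozygous
    "chrT\t251\t.\tG\tGA\t.\tPASS\t.\tGT\t0/1",  # indel
    "chrU\t51\t.\tT\tC\t.\tPASS\t.\tGT\t0|1")
  writeLines(lines, path)
  path
}
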