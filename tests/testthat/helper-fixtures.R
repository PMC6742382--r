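# Builders for small call tables and callsets used across the test files.

mk_calls <- function(n = 1, sample_id = "S1", gene = "G1", chrom = "1",
                     pos = NULL, ref_allele = "A", alt_allele = "T",
                     variant_class = "Missense", protein_change = "",
                     alt_count = NA_integer_, ref_count = NA_integer_,
                     population_af = NA_real_, in_cpg_island = NA) {
  if (is.null(pos)) pos <- seq_len(n)
  tibble::tibble(sample_id = sample_id, gene = gene, chrom = chrom, pos = pos,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 variant_class = variant_class,
                 protein_change = protein_change,
                 alt_count = alt_count, ref_count = ref_count,
                 population_af = population_af, in_cpg_island = in_cpg_island)
}

# A callset with n distinct keys at a given maf (via read counts at depth),
# with keys indexed by `ids` so overlapping sets are easy to construct.
keyset_callset <- function(ids, label, maf = 0.5, depth = 1000,
                           gene = "G1", cpg = FALSE, sample_id = "S1") {
  n <- length(ids)
  maf <- rep_len(maf, n)
  depth <- rep_len(depth, n)
  alt <- as.integer(round(maf * depth))
  callset(mk_calls(n, sample_id = sample_id, gene = rep_len(gene, n),
                   pos = as.integer(ids),
                   alt_count = alt, ref_count = as.integer(depth) - alt,
                   in_cpg_island = rep_len(cpg, n)),
          source_label = label)
}

# Random multi-sample callset for oracle comparisons; duplicates possible
# before dedup, so keys are taken from the constructed set itself.
random_callset <- function(n, label, seed, n_samples = 5, n_pos = 400,
                           maf_range = c(0.01, 0.9)) {
  set.seed(seed)
  depth <- sample(50:2000, n, replace = TRUE)
  maf <- runif(n, maf_range[1], maf_range[2])
  alt <- pmax(1L, as.integer(round(maf * depth)))
  callset(mk_calls(
    n,
    sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n, replace = TRUE),
    gene = sample(sprintf("G%02d", 1:20), n, replace = TRUE),
    chrom = sample(as.character(1:5), n, replace = TRUE),
    pos = sample.int(n_pos, n, replace = TRUE),
    alt_count = alt, ref_count = depth - alt),
    source_label = label)
}

write_tsv_text <- function(lines, file = tempfile(fileext = ".maf")) {
  writeLines(lines, file)
  file
}

maf_header <- paste("Hugo_Symbol", "Chromosome", "Start_position",
                    "Reference_Allele", "Tumor_Seq_Allele2",
                    "Variant_Classification", "Tumor_Sample_Barcode",
                    "Protein_Change", "t_alt_count", "t_ref_count",
                    sep = "\t")

maf_row <- function(gene = "TP53", chrom = "17", pos = 100, ref = "C",
                    alt = "T", class = "Missense_Mutation", sample = "S1",
                    protein = "p.R175H", alt_count = 40, ref_count = 60) {
  paste(gene, chrom, pos, ref, alt, class, sample, protein,
        alt_count, ref_count, sep = "\t")
}
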