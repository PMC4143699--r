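# Small in-code fixtures shared across test files.

write_tmp_lines <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# father, mother, child
trio_ped_lines <- c("FAM1 F 0 0 1 0",
                    "FAM1 M 0 0 2 0",
                    "FAM1 C F M 1 0")

# minimal GT-only VCF text
make_vcf_lines <- function(samples, records) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT",
            r$gt), collapse = "\t")
  }, character(1))
  c(header, body)
}

# a pedigree of founders only (for founder-frequency fixtures)
founder_ped <- function(ids) {
  pedigree(data.frame(family_id = "FAM1", individual_id = ids,
                      father_id = "0", mother_id = "0",
                      sex = rep(c("1", "2"), length.out = length(ids)),
                      stringsAsFactors = FALSE))
}

# one nuclear family (two founder parents, given offspring ids)
family_ped <- function(offspring = c("C1", "C2")) {
  pedigree(data.frame(
    family_id = "FAM1",
    individual_id = c("F", "M", offspring),
    father_id = c("0", "0", rep("F", length(offspring))),
    mother_id = c("0", "0", rep("M", length(offspring))),
    sex = c("1", "2", rep("1", length(offspring))),
    stringsAsFactors = FALSE))
}

# genotype_matrix from an explicit counts matrix (minor allele = alt)
gm_from_counts <- function(counts, chrom = "3", pos = NULL, ped = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(counts)) * 1000L
  variants <- data.frame(
    variant_id = colnames(counts), chrom = chrom, pos = pos,
    ref = "A", alt = "C", minor_allele = "alt", founder_maf = NA_real_,
    stringsAsFactors = FALSE)
  if (is.null(ped)) {
    gm <- genotype_matrix(variants, counts)
    gm$variants$founder_maf <- colMeans(counts, na.rm = TRUE) / 2
    gm
  } else {
    fbatrare:::orient_minor_allele(variants, counts, ped)
  }
}

# memoised heavy simulations shared by the acceptance suite
.sim_cache <- new.env(parent = emptyenv())
cached_dataset <- function(preset, seed) {
  key <- paste(preset, seed, sep = "_")
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_dataset(make_gaw_like_scenario(preset, seed = seed))
  }
  .sim_cache[[key]]
}
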