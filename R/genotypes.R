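#' Construct a genotype matrix container
#'
#' Holds per-individual minor-allele counts for an ordered set of biallelic
#' variants, with the minor allele oriented against the founder population.
#'
#' @param variants Data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based, as in VCF), `ref`, `alt`, `minor_allele` (`"ref"` or `"alt"`)
#'   and `founder_maf` (`NA` when no founder is typed).
#' @param counts Integer matrix of minor-allele counts in \{0, 1, 2, NA\},
#'   individuals in rows (rownames = individual ids), variants in columns
#'   (colnames = `variant_id`).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(variants, counts) {
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "minor_allele", "founder_maf")
  stopifnot(is.data.frame(variants), all(need %in% names(variants)),
            is.matrix(counts), ncol(counts) == nrow(variants),
            identical(colnames(counts), as.character(variants$variant_id)),
            !is.null(rownames(counts)))
  bad <- !(counts %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype counts must be 0, 1, 2 or NA", call. = FALSE)
  maf <- variants$founder_maf
  if (any(!is.na(maf) & (maf < 0 | maf > 0.5))) {
    stop("founder_maf must lie in [0, 0.5] after minor-allele orientation",
         call. = FALSE)
  }
  rownames(variants) <- NULL
  structure(list(variants = variants, counts = counts), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%s)\n",
              nrow(x$counts), nrow(x$variants),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' Reads biallelic GT records with vcfR, orients each variant so that counts
#' refer to the minor allele in the *founder* population (tie at 0.5 kept as
#' alt), and stores the resulting founder minor allele frequency.
#' Multiallelic records are skipped with a message; VCF samples not in the
#' pedigree are ignored with a warning; pedigree members absent from the VCF
#' get missing genotypes.
#'
#' @param path VCF file (plain or bgzipped).
#' @param ped A `fbat_pedigree`; founder status drives allele orientation.
#' @param region Optional one-row region (`chrom`, `start`, `end`, 0-based
#'   half-open); only variants inside it are kept.  VCF positions are
#'   converted by subtracting 1 before intersection.
#' @return A [genotype_matrix()] whose rows follow the pedigree order.
#' @export
read_genotypes <- function(path, ped, region = NULL) {
  stopifnot(inherits(ped, "fbat_pedigree"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {  # single record comes back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no records", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) {
    gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) skipped")
  }
  keep <- !multi
  pos <- as.integer(fix$POS)
  if (!is.null(region)) {
    region <- as.data.frame(region)
    keep <- keep & fix$CHROM == as.character(region$chrom[1L]) &
      (pos - 1L) >= region$start[1L] & (pos - 1L) < region$end[1L]
  }
  if (!any(keep)) stop("no usable VCF records after filtering", call. = FALSE)
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  gt <- gt[keep, , drop = FALSE]

  samples <- colnames(gt)
  shared <- intersect(ped$individual_id, samples)
  if (!length(shared)) {
    stop("no VCF sample id matches the pedigree", call. = FALSE)
  }
  extra <- setdiff(samples, ped$individual_id)
  if (length(extra)) {
    warning(length(extra), " VCF sample(s) not in the pedigree ignored",
            call. = FALSE)
  }

  alt_counts <- gt_to_alt_counts(gt)
  counts <- matrix(NA_integer_, nrow = nrow(ped), ncol = nrow(fix),
                   dimnames = list(ped$individual_id, NULL))
  counts[shared, ] <- t(alt_counts[, shared, drop = FALSE])

  id <- fix$ID
  blank <- is.na(id) | id == "." | id == ""
  id[blank] <- paste0(fix$CHROM[blank], ":", pos[blank], "_",
                      fix$REF[blank], "_", fix$ALT[blank])
  variants <- data.frame(variant_id = id, chrom = fix$CHROM, pos = pos,
                         ref = fix$REF, alt = fix$ALT,
                         minor_allele = "alt", founder_maf = NA_real_,
                         stringsAsFactors = FALSE)
  colnames(counts) <- variants$variant_id

  orient_minor_allele(variants, counts, ped)
}

# GT strings ("0/0", "0|1", ".", "./.") -> ALT allele counts; any genotype
# containing a missing allele becomes NA.
gt_to_alt_counts <- function(gt) {
  g <- gsub("|", "/", gt, fixed = TRUE)
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  out <- lut[g]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

# Flip variants whose founder ALT frequency exceeds 0.5 so counts always
# refer to the founder minor allele, and record the founder MAF.
orient_minor_allele <- function(variants, counts, ped) {
  fnd <- intersect(founders(ped), rownames(counts))
  fc <- counts[fnd, , drop = FALSE]
  typed <- colSums(!is.na(fc))
  falt <- ifelse(typed > 0L, colSums(fc, na.rm = TRUE) / (2 * typed), NA_real_)
  flip <- !is.na(falt) & falt > 0.5
  if (any(flip)) {
    counts[, flip] <- 2L - counts[, flip]
    variants$minor_allele[flip] <- "ref"
  }
  variants$founder_maf <- ifelse(flip, 1 - falt, falt)
  genotype_matrix(variants, counts)
}

#' Founder minor allele frequency per variant
#'
#' The frequency of the minor allele among the founders of the pedigree:
#' minor-allele copies divided by twice the number of founders typed at the
#' variant.  Variants with no typed founder are `NA` (flagged and excluded
#' from downstream rare-variant selection).
#'
#' @param gm A [genotype_matrix()].
#' @param ped The `fbat_pedigree` the matrix was read against.
#' @return Named numeric vector (one entry per variant) in \[0, 0.5\].
#' @export
founder_minor_allele_freq <- function(gm, ped) {
  fnd <- intersect(founders(ped), rownames(gm$counts))
  fc <- gm$counts[fnd, , drop = FALSE]
  typed <- colSums(!is.na(fc))
  out <- ifelse(typed > 0L, colSums(fc, na.rm = TRUE) / (2 * typed), NA_real_)
  names(out) <- gm$variants$variant_id
  out
}

#' Subset a genotype matrix by variant id
#'
#' @param gm A [genotype_matrix()].
#' @param variant_ids Variant ids to keep, in the requested order.
#' @return A [genotype_matrix()] restricted to those variants.
#' @export
subset_variants <- function(gm, variant_ids) {
  idx <- match(variant_ids, gm$variants$variant_id)
  if (anyNA(idx)) {
    stop("unknown variant id(s): ",
         paste(variant_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  genotype_matrix(gm$variants[idx, , drop = FALSE],
                  gm$counts[, idx, drop = FALSE])
}

#' Write a genotype matrix to a minimal VCF file
#'
#' Emits a VCFv4.2 file with GT-only FORMAT, one sample column per
#' individual, counts re-expressed on the ALT allele.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  alt_counts <- gm$counts
  flip <- v$minor_allele == "ref"
  if (any(flip)) alt_counts[, flip] <- 2L - alt_counts[, flip]
  gt_lut <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", unique(v$chrom), ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(alt_counts)), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    g <- alt_counts[, i]
    gs <- ifelse(is.na(g), "./.", gt_lut[g + 1L])
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i],
            ".", "PASS", ".", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED-style region file
#'
#' Four whitespace-delimited columns: chrom, start, end (0-based half-open),
#' name.
#'
#' @param path Region file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
read_regions <- function(path) {
  r <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#",
                         col.names = c("chrom", "start", "end", "name"),
                         colClasses = c("character", "integer", "integer", "character"))
  if (any(r$start < 0L) || any(r$start >= r$end)) {
    stop("regions require 0 <= start < end", call. = FALSE)
  }
  r
}

#' Count Mendelian inconsistencies in parent-offspring trios
#'
#' For every nonfounder with both parents typed at a variant, checks that
#' the offspring count is reachable under Mendelian transmission (a parent
#' with count 0 transmits 0, count 2 transmits 1, count 1 transmits either).
#'
#' @param gm A [genotype_matrix()].
#' @param ped The matching `fbat_pedigree`.
#' @return Integer: number of (offspring, variant) pairs violating
#'   Mendelian transmission among fully typed trios.
#' @export
count_mendelian_errors <- function(gm, ped) {
  off <- ped[!ped$founder, ]
  if (!nrow(off)) return(0L)
  C <- gm$counts
  oc <- C[off$individual_id, , drop = FALSE]
  fc <- C[off$father_id, , drop = FALSE]
  mc <- C[off$mother_id, , drop = FALSE]
  lo <- (fc == 2L) + (mc == 2L)
  hi <- (fc > 0L) + (mc > 0L)
  bad <- !is.na(oc) & !is.na(fc) & !is.na(mc) & (oc < lo | oc > hi)
  sum(bad)
}
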