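#' Read a PED/FAM-style pedigree file
#'
#' Parses a whitespace-delimited pedigree file with columns
#' family id, individual id, father id, mother id, sex, and optionally a
#' phenotype column (ignored).  `"0"` denotes a missing parent.  Sex is
#' coded `1` = male, `2` = female, anything else = unknown.
#'
#' @param path Path to the pedigree text file.
#' @return A `fbat_pedigree` data frame with columns `family_id`,
#'   `individual_id`, `father_id`, `mother_id` (`NA` when missing), `sex`
#'   (integer 1/2/0) and `founder` (logical), plus a `generation` column
#'   giving the generation depth (founders = 1).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) {
    stop("pedigree file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 5L) {
    stop("pedigree file must have >= 5 whitespace-delimited columns ",
         "(family, individual, father, mother, sex)", call. = FALSE)
  }
  pedigree(data.frame(family_id = raw[[1L]], individual_id = raw[[2L]],
                      father_id = raw[[3L]], mother_id = raw[[4L]],
                      sex = raw[[5L]], stringsAsFactors = FALSE))
}

#' Construct and validate a pedigree
#'
#' Validates parental links (an individual with exactly one known parent is
#' rejected), checks that every referenced parent exists in the same family,
#' and that the parentage graph is acyclic.  Exact duplicate rows are
#' dropped; conflicting duplicate individual ids are an error.
#'
#' @param df Data frame with character columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` and `sex`.  `"0"`, `""` and `NA` in the parent
#'   columns denote a missing parent.
#' @return A validated `fbat_pedigree` data frame (see [read_pedigree()]).
#' @export
pedigree <- function(df) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  if (!all(need %in% names(df))) {
    stop("pedigree needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- unique(df[, need])
  for (col in c("father_id", "mother_id")) {
    v <- as.character(df[[col]])
    v[v %in% c("0", "")] <- NA_character_
    df[[col]] <- v
  }
  df$family_id <- as.character(df$family_id)
  df$individual_id <- as.character(df$individual_id)

  one_parent <- is.na(df$father_id) != is.na(df$mother_id)
  if (any(one_parent)) {
    stop("individual(s) with exactly one known parent: ",
         paste(df$individual_id[one_parent], collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df$individual_id)
  if (any(dup)) {
    stop("conflicting duplicate individual id(s): ",
         paste(unique(df$individual_id[dup]), collapse = ", "), call. = FALSE)
  }

  sex_raw <- toupper(as.character(df$sex))
  df$sex <- ifelse(sex_raw %in% c("1", "M", "MALE"), 1L,
            ifelse(sex_raw %in% c("2", "F", "FEMALE"), 2L, 0L))

  # every referenced parent must exist within the same family
  for (col in c("father_id", "mother_id")) {
    ref <- !is.na(df[[col]])
    key_parent <- paste(df$family_id[ref], df[[col]][ref])
    key_all <- paste(df$family_id, df$individual_id)
    missing_parent <- !(key_parent %in% key_all)
    if (any(missing_parent)) {
      stop("referenced ", sub("_id", "", col), "(s) absent from pedigree: ",
           paste(unique(df[[col]][ref][missing_parent]), collapse = ", "),
           call. = FALSE)
    }
  }

  df$founder <- is.na(df$father_id)
  df <- df[order(df$family_id, df$individual_id), ]
  rownames(df) <- NULL
  df$generation <- generation_depth(df)
  class(df) <- c("fbat_pedigree", "data.frame")
  df
}

# Generation depth of each individual: founders are generation 1, an
# offspring is one deeper than its deepest parent.  Non-convergence after
# n iterations means the parentage graph has a cycle.
generation_depth <- function(df) {
  depth <- ifelse(is.na(df$father_id), 1L, NA_integer_)
  names(depth) <- df$individual_id
  for (iter in seq_len(nrow(df) + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) {
      return(unname(depth))
    }
    fd <- depth[df$father_id[todo]]
    md <- depth[df$mother_id[todo]]
    ready <- !is.na(fd) & !is.na(md)
    if (!any(ready)) {
      stop("cyclic parentage involving: ",
           paste(df$individual_id[todo], collapse = ", "), call. = FALSE)
    }
    depth[todo[ready]] <- pmax(fd[ready], md[ready]) + 1L
  }
  stop("cyclic parentage detected", call. = FALSE)
}

#' Founder individuals of a pedigree
#'
#' @param ped A `fbat_pedigree`.
#' @return Character vector of individual ids with no parents in the pedigree.
#' @export
founders <- function(ped) {
  stopifnot(inherits(ped, "fbat_pedigree"))
  ped$individual_id[ped$founder]
}

#' @export
print.fbat_pedigree <- function(x, ...) {
  cat(sprintf("fbat_pedigree: %d individuals in %d famil%s (%d founders, max generation %d)\n",
              nrow(x), length(unique(x$family_id)),
              if (length(unique(x$family_id)) == 1L) "y" else "ies",
              sum(x$founder), max(x$generation)))
  invisible(x)
}

#' Decompose extended pedigrees into nuclear families
#'
#' A nuclear family is one father-mother pair together with all their common
#' offspring; it is the conditioning unit of the FBAT statistic and the unit
#' counted by the v1 weight denominator (zeta).  Every individual whose
#' parents are known appears as an offspring in exactly one nuclear family
#' (the one formed by its own parents); an individual with offspring by
#' several mates appears as a parent in several families.
#'
#' @param ped A `fbat_pedigree`.
#' @return A `nuclear_families` data frame in long format with columns
#'   `nuc_id` (integer), `family_id`, `father_id`, `mother_id` and
#'   `offspring_id`, sorted by (family, father, mother, offspring).  The
#'   number of distinct families is in attribute `n_families` and via
#'   [n_nuclear_families()].
#' @export
decompose_nuclear_families <- function(ped) {
  stopifnot(inherits(ped, "fbat_pedigree"))
  off <- ped[!ped$founder, c("family_id", "father_id", "mother_id", "individual_id")]
  names(off)[4L] <- "offspring_id"
  off <- off[order(off$family_id, off$father_id, off$mother_id, off$offspring_id), ]
  key <- paste(off$family_id, off$father_id, off$mother_id, sep = "\r")
  off$nuc_id <- if (nrow(off)) match(key, unique(key)) else integer(0)
  off <- off[, c("nuc_id", "family_id", "father_id", "mother_id", "offspring_id")]
  rownames(off) <- NULL
  attr(off, "n_families") <- length(unique(off$nuc_id))
  class(off) <- c("nuclear_families", "data.frame")
  off
}

#' Total number of nuclear families
#'
#' This count is the zeta entering the v1 (Madsen-Browning style) weight.
#'
#' @param nucs A `nuclear_families` object from [decompose_nuclear_families()].
#' @return Integer count of distinct father-mother pairs with offspring.
#' @export
n_nuclear_families <- function(nucs) {
  stopifnot(inherits(nucs, "nuclear_families"))
  attr(nucs, "n_families")
}
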