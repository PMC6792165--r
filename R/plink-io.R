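#' Read PLINK genotype files
#'
#' Reads either text PED/MAP or binary BED/BIM/FAM (SNP-major) into a
#' [genotype_dataset()]. Breed labels are taken from the family-ID column
#' (first field of PED/FAM), the usual convention for multi-breed HapMap
#' panels. Variants are sorted by (chromosome, position) on read with a
#' stable sort; unsorted input is accepted.
#'
#' Call coding is the count of `allele_a1`. For BED/BIM input, A1/A2 are the
#' BIM columns 5 and 6. PED/MAP files carry no allele columns, so A1 is
#' defined as the alphabetically first allele observed at the SNP (and A2 the
#' other, or "0" if monomorphic); this rule is deterministic and stable under
#' write/read round trips. Note the text format cannot represent an allele
#' absent from the sample set, so a dataset round-trips through PED/MAP with
#' its original A1/A2 orientation only at SNPs where both alleles are
#' observed; BED/BIM preserves orientation unconditionally.
#'
#' Chromosome codes X, Y, XY, MT are mapped to 27, 28, 29, 30; unrecognised
#' codes map to 0 (unplaced). Any code outside 1..26 is non-autosomal for
#' [filter_variants()].
#'
#' @param path_prefix path stem; `<prefix>.ped/.map` or `<prefix>.bed/.bim/.fam`
#'   must exist.
#' @param format `"ped"` or `"bed"`.
#' @return a `genotype_dataset`
#' @export
read_plink <- function(path_prefix, format = c("ped", "bed")) {
  format <- match.arg(format)
  if (format == "ped") read_plink_ped(path_prefix) else read_plink_bed(path_prefix)
}

chrom_code <- function(x) {
  up <- toupper(as.character(x))
  code <- suppressWarnings(as.integer(up))
  special <- c(X = 27L, Y = 28L, XY = 29L, MT = 30L)
  code[is.na(code) & up %in% names(special)] <- special[up[is.na(code) & up %in% names(special)]]
  code[is.na(code)] <- 0L
  code
}

chrom_label <- function(code) {
  lab <- as.character(code)
  lab[code == 27L] <- "X"
  lab[code == 28L] <- "Y"
  lab[code == 29L] <- "XY"
  lab[code == 30L] <- "MT"
  lab
}

require_file <- function(path) {
  if (!file.exists(path)) stop("missing companion file: ", path, call. = FALSE)
  path
}

read_map_file <- function(path) {
  map <- data.table::fread(require_file(path), header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(map) < 4L) stop("malformed MAP/BIM file (", path, "): expected >= 4 columns")
  data.frame(
    chrom = chrom_code(map[[1]]),
    id = map[[2]],
    pos_bp = as.double(map[[4]]),
    stringsAsFactors = FALSE
  )
}

read_plink_ped <- function(path_prefix) {
  map <- read_map_file(paste0(path_prefix, ".map"))
  ped_path <- require_file(paste0(path_prefix, ".ped"))
  m <- nrow(map)
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (nrow(ped) == 0L) {
    tok <- matrix(character(0), 0L, 2L * m)
    fam <- ind <- character(0)
  } else {
    if (ncol(ped) != 6L + 2L * m) {
      stop("malformed PED file (", ped_path, "): ", ncol(ped),
           " fields per line, expected ", 6L + 2L * m)
    }
    fam <- ped[[1]]
    ind <- ped[[2]]
    tok <- as.matrix(ped[, -(1:6), drop = FALSE])
  }
  allowed <- c("A", "C", "G", "T", "0")
  if (length(tok) && !all(tok %in% allowed)) {
    bad <- which(matrix(!(tok %in% allowed), nrow(tok)), arr.ind = TRUE)[1, ]
    stop("malformed genotype token '", tok[bad[1], bad[2]], "' at line ", bad[1],
         ", allele field ", bad[2], " of ", ped_path)
  }
  n <- length(ind)
  calls <- matrix(NA_integer_, n, m)
  a1 <- a2 <- rep("0", m)
  for (j in seq_len(m)) {
    x1 <- tok[, 2L * j - 1L]
    x2 <- tok[, 2L * j]
    half_missing <- xor(x1 == "0", x2 == "0")
    if (any(half_missing)) {
      stop("malformed genotype (half-missing) at line ", which(half_missing)[1],
           ", SNP ", map$id[j], " of ", ped_path)
    }
    obs <- sort(unique(c(x1, x2)))
    obs <- obs[obs != "0"]
    if (length(obs) > 2L) {
      stop("more than two alleles (", paste(obs, collapse = "/"), ") at SNP ",
           map$id[j], " of ", ped_path)
    }
    if (length(obs) >= 1L) a1[j] <- obs[1]
    if (length(obs) == 2L) a2[j] <- obs[2]
    cj <- (x1 == a1[j]) + (x2 == a1[j])
    cj[x1 == "0"] <- NA_integer_
    calls[, j] <- as.integer(cj)
  }
  samples <- data.frame(sample_id = ind, breed = fam, stringsAsFactors = FALSE)
  variants <- data.frame(id = map$id, chrom = map$chrom, pos_bp = map$pos_bp,
                         a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_dataset(samples, variants, calls)
}

# 2-bit BED genotype codes (per sample slot, SNP-major):
#   00 -> hom A1 (call 2), 01 -> missing, 10 -> het, 11 -> hom A2 (call 0)
bed_code_to_call <- c(2L, NA_integer_, 1L, 0L)
bed_call_to_code <- function(call) {
  code <- integer(length(call))
  code[is.na(call)] <- 1L
  code[!is.na(call) & call == 2L] <- 0L
  code[!is.na(call) & call == 1L] <- 2L
  code[!is.na(call) & call == 0L] <- 3L
  code
}

read_plink_bed <- function(path_prefix) {
  bim <- data.table::fread(require_file(paste0(path_prefix, ".bim")), header = FALSE,
                           colClasses = "character", data.table = FALSE)
  if (ncol(bim) < 6L) stop("malformed BIM file: expected 6 columns")
  fam <- data.table::fread(require_file(paste0(path_prefix, ".fam")), header = FALSE,
                           colClasses = "character", data.table = FALSE)
  bed_path <- require_file(paste0(path_prefix, ".bed"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("bad BED magic bytes at offset 0 of ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("BED file ", bed_path, " is not SNP-major (mode byte at offset 2 is ",
         as.integer(raw[3]), ", expected 1)")
  }
  bpv <- ceiling(n / 4)            # bytes per variant
  if (length(raw) != 3L + bpv * m) {
    stop("BED file ", bed_path, " has ", length(raw), " bytes, expected ",
         3L + bpv * m)
  }
  calls <- matrix(NA_integer_, n, m)
  if (n > 0L && m > 0L) {
    body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv)   # bytes x variants
    slot <- (seq_len(n) - 1L) %% 4L                        # bit-pair within byte
    byte <- ((seq_len(n) - 1L) %/% 4L) + 1L
    for (k in 0:3) {
      rows <- which(slot == k)
      if (!length(rows)) next
      codes <- (body[byte[rows], , drop = FALSE] %/% (4L^k)) %% 4L
      calls[rows, ] <- matrix(bed_code_to_call[codes + 1L], length(rows))
    }
  }
  samples <- data.frame(sample_id = fam[[2]], breed = fam[[1]], stringsAsFactors = FALSE)
  variants <- data.frame(id = bim[[2]], chrom = chrom_code(bim[[1]]),
                         pos_bp = as.double(bim[[4]]),
                         a1 = bim[[5]], a2 = bim[[6]], stringsAsFactors = FALSE)
  genotype_dataset(samples, variants, calls)
}

#' Write PLINK genotype files
#'
#' Writes a [genotype_dataset()] as standard PED/MAP text or SNP-major
#' BED/BIM/FAM binary (magic bytes 6C 1B, mode byte 01). Missing calls are
#' written as "0 0" in text and binary code 01. The breed label is written to
#' the family-ID column; paternal/maternal/sex/phenotype fields are written as
#' 0 (unknown).
#'
#' @param dataset a `genotype_dataset`
#' @inheritParams read_plink
#' @return `path_prefix`, invisibly
#' @export
write_plink <- function(dataset, path_prefix, format = c("ped", "bed")) {
  format <- match.arg(format)
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) stop("unwritable path: directory ", dir, " does not exist")
  v <- dataset$variants
  s <- dataset$samples
  map <- data.frame(chrom_label(v$chrom), v$id, 0L, format(v$pos_bp, scientific = FALSE, trim = TRUE))
  if (format == "ped") {
    data.table::fwrite(map, paste0(path_prefix, ".map"), sep = "\t", col.names = FALSE)
    n <- nrow(s); m <- nrow(v)
    lines <- character(n)
    if (n > 0L) {
      gtok <- matrix("", n, 2L * m)
      if (m > 0L) {
        calls <- dataset$calls
        A1 <- matrix(v$a1, n, m, byrow = TRUE)
        A2 <- matrix(v$a2, n, m, byrow = TRUE)
        t1 <- ifelse(is.na(calls), "0", ifelse(calls >= 1L, A1, A2))
        t2 <- ifelse(is.na(calls), "0", ifelse(calls == 2L, A1, A2))
        gtok[, seq(1L, 2L * m, by = 2L)] <- t1
        gtok[, seq(2L, 2L * m, by = 2L)] <- t2
      }
      lead <- cbind(s$breed, s$sample_id, "0", "0", "0", "-9")
      lines <- apply(cbind(lead, gtok), 1L, paste, collapse = " ")
    }
    writeLines(lines, paste0(path_prefix, ".ped"))
  } else {
    data.table::fwrite(
      data.frame(map[[1]], map[[2]], map[[3]], map[[4]], v$a1, v$a2),
      paste0(path_prefix, ".bim"), sep = "\t", col.names = FALSE
    )
    data.table::fwrite(
      data.frame(s$breed, s$sample_id, 0L, 0L, 0L, -9L),
      paste0(path_prefix, ".fam"), sep = " ", col.names = FALSE
    )
    n <- nrow(s); m <- nrow(v)
    bpv <- ceiling(n / 4)
    con <- file(paste0(path_prefix, ".bed"), "wb")
    on.exit(close(con))
    writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
    if (m > 0L && n > 0L) {
      codes <- matrix(bed_call_to_code(dataset$calls), n, m)   # n x m
      pad <- 4L * bpv - n
      if (pad > 0L) codes <- rbind(codes, matrix(0L, pad, m))
      mult <- 4L^((seq_len(4L * bpv) - 1L) %% 4L)
      grp <- rep(seq_len(bpv), each = 4L)
      bytes <- rowsum(codes * mult, grp)                       # bpv x m
      writeBin(as.raw(as.vector(bytes)), con)
    }
  }
  invisible(path_prefix)
}

#' Filter variants to positioned autosomal SNPs
#'
#' Retains exactly the variants with `1 <= chrom <= autosome_max` and a
#' positive physical position, i.e. removes SNPs lacking positional
#' information, SNPs unassigned to any chromosome, and sex-chromosome SNPs.
#' The sample set is unchanged. The accompanying report partitions every
#' removal and gives the post-filter genotyping rate.
#'
#' @param dataset a `genotype_dataset`
#' @param autosome_max highest autosome code (26 for sheep, OAR1-OAR26)
#' @return list with elements `dataset` (filtered) and `report` (class
#'   `filter_report`: n_input, n_removed_no_position, n_removed_unassigned,
#'   n_removed_sex_chrom, n_retained, genotyping_rate)
#' @export
filter_variants <- function(dataset, autosome_max = 26L) {
  v <- dataset$variants
  no_pos <- v$pos_bp <= 0
  unassigned <- !no_pos & v$chrom == 0L
  sex <- !no_pos & !unassigned & (v$chrom > autosome_max)
  keep <- !(no_pos | unassigned | sex)
  out <- subset_dataset(dataset, variants = which(keep))
  ncalls <- length(out$calls)
  report <- structure(list(
    n_input = nrow(v),
    n_removed_no_position = sum(no_pos),
    n_removed_unassigned = sum(unassigned),
    n_removed_sex_chrom = sum(sex),
    n_retained = sum(keep),
    genotyping_rate = if (ncalls) 1 - sum(is.na(out$calls)) / ncalls else NA_real_
  ), class = "filter_report")
  list(dataset = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("variant filter: ", x$n_input, " in, ", x$n_retained, " retained\n",
      "  removed: no position ", x$n_removed_no_position,
      ", unassigned ", x$n_removed_unassigned,
      ", sex chromosome ", x$n_removed_sex_chrom, "\n",
      sprintf("  genotyping rate (retained): %.4f\n", x$genotyping_rate), sep = "")
  invisible(x)
}

#' Write a filter report as TSV
#' @param report a `filter_report`
#' @param path output file
#' @export
write_filter_report <- function(report, path) {
  data.table::fwrite(as.data.frame(unclass(report)), path, sep = "\t")
  invisible(path)
}
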