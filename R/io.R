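#' Read a genotype matrix from PED/MAP or VCF
#'
#' @param path for `format = "ped_map"`, the path prefix (reads
#'   `<prefix>.ped` and `<prefix>.map`) or the `.ped` path; for
#'   `format = "vcf"`, a VCF file.
#' @param format `"ped_map"` or `"vcf"` (guessed from the extension when
#'   missing).
#' @return a `genotype_matrix` (see [emit_snp_genotypes()]). Alleles not
#'   matching the marker's two known alleles are set missing, with a
#'   counted warning.
#' @export
read_genotypes <- function(path, format = c("auto", "ped_map", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "ped_map"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_ped(path)
}

read_genotypes_ped <- function(path) {
  prefix <- sub("\\.ped$", "", path)
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)
  map <- tryCatch(
    data.table::fread(map_path, header = FALSE, colClasses = list(character = c(1, 2)),
                      data.table = FALSE),
    error = function(e) stop("malformed MAP file ", map_path, ": ", conditionMessage(e)))
  if (ncol(map) != 4) stop("MAP file ", map_path, " must have 4 columns")
  names(map) <- c("chrom", "id", "cm", "pos")
  ped <- tryCatch(
    data.table::fread(ped_path, header = FALSE, colClasses = "character",
                      data.table = FALSE),
    error = function(e) stop("malformed PED file ", ped_path, ": ", conditionMessage(e)))
  n_mark <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_mark) {
    nline <- which(vapply(seq_len(nrow(ped)), function(i)
      any(is.na(ped[i, ])), logical(1)))
    stop("PED file ", ped_path, " line ", if (length(nline)) nline[1] else 1,
         ": expected ", 6 + 2 * n_mark, " fields")
  }
  ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_mark) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_mark), drop = FALSE])
  # marker ids written as chrom_pos_ref_alt carry allele orientation
  idp <- strsplit(map$id, "_")
  oriented <- lengths(idp) == 4
  ref <- ifelse(oriented, vapply(idp, function(x) x[3], character(1)), NA)
  alt <- ifelse(oriented, vapply(idp, function(x) x[4], character(1)), NA)
  n_unknown <- 0L
  calls <- matrix(NA_integer_, nrow(ped), n_mark, dimnames = list(ids, map$id))
  for (k in seq_len(n_mark)) {
    if (is.na(ref[k])) {  # fall back to order of appearance
      seen <- setdiff(unique(c(a1[, k], a2[, k])), "0")
      ref[k] <- if (length(seen)) seen[1] else "N"
      alt[k] <- if (length(seen) > 1) seen[2] else "N"
    }
    s1 <- match(a1[, k], c(ref[k], alt[k])) - 1L
    s2 <- match(a2[, k], c(ref[k], alt[k])) - 1L
    missing <- a1[, k] == "0" | a2[, k] == "0"
    unknown <- (is.na(s1) | is.na(s2)) & !missing
    n_unknown <- n_unknown + sum(unknown)
    g <- s1 + s2
    g[missing | unknown] <- NA_integer_
    calls[, k] <- g
  }
  if (n_unknown > 0)
    warning(n_unknown, " allele(s) not matching the marker's known alleles; set missing")
  markers <- data.frame(chrom = map$chrom, pos = as.numeric(map$pos), id = map$id,
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
  structure(list(calls = calls, markers = markers), class = "genotype_matrix")
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x == "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x == "1/1"] <- 2L
    out
  }
  calls <- t(matrix(code(gt), nrow = nrow(gt), ncol = ncol(gt)))  # ind x markers
  rownames(calls) <- colnames(gt)
  markers <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                        id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  miss_id <- is.na(markers$id) | markers$id == "."
  markers$id[miss_id] <- sprintf("%s_%d_%s_%s", markers$chrom[miss_id],
                                 markers$pos[miss_id], markers$ref[miss_id],
                                 markers$alt[miss_id])
  colnames(calls) <- markers$id
  structure(list(calls = calls, markers = markers), class = "genotype_matrix")
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' Marker IDs are written as `chrom_pos_ref_alt` so that allele
#' orientation round-trips; genotypes use the marker's ref/alt bases,
#' missing calls `0 0`.
#'
#' @param matrix a `genotype_matrix`.
#' @param pedigree a [pedigree] supplying family/parent/sex/affection
#'   columns.
#' @param prefix output path prefix (writes `<prefix>.ped`, `<prefix>.map`).
#' @export
write_ped_map <- function(matrix, pedigree, prefix) {
  mk <- matrix$markers
  map <- data.frame(chrom = mk$chrom, id = mk$id, cm = 0, pos = mk$pos)
  data.table::fwrite(map, paste0(prefix, ".map"), sep = "\t", col.names = FALSE)
  ids <- rownames(matrix$calls)
  pr <- pedigree[match(ids, pedigree$id), ]
  n <- ncol(matrix$calls)
  al <- matrix("0", nrow = length(ids), ncol = 2 * n)
  for (k in seq_len(n)) {
    g <- matrix$calls[, k]
    al[, 2 * k - 1] <- ifelse(is.na(g), "0", ifelse(g >= 1, mk$alt[k], mk$ref[k]))
    al[, 2 * k] <- ifelse(is.na(g), "0", ifelse(g == 2, mk$alt[k], mk$ref[k]))
  }
  lead <- data.frame(fid = pr$family, iid = ids,
                     pat = ifelse(is.na(pr$father), "0", pr$father),
                     mat = ifelse(is.na(pr$mother), "0", pr$mother),
                     sex = ifelse(pr$sex == "male", 1L, 2L),
                     pheno = ifelse(pr$affected, 2L, 1L),
                     stringsAsFactors = FALSE)
  data.table::fwrite(cbind(lead, as.data.frame(al)), paste0(prefix, ".ped"),
                     sep = " ", col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

vcf_header <- function(sample_ids, seed = NULL, info_lines = character(0)) {
  c("##fileformat=VCFv4.2",
    "##source=autozygmap",
    if (!is.null(seed)) sprintf("##simulation_seed=%d", seed),
    info_lines,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))
}

gt_string <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0] <- "0/0"
  out[!is.na(g) & g == 1] <- "0/1"
  out[!is.na(g) & g == 2] <- "1/1"
  out
}

#' Write a genotype matrix as VCF
#'
#' @param matrix a `genotype_matrix`.
#' @param path output `.vcf` path.
#' @param seed simulation seed recorded in the header, if any.
#' @export
write_vcf <- function(matrix, path, seed = NULL) {
  ids <- rownames(matrix$calls)
  mk <- matrix$markers
  gt <- apply(matrix$calls, 1, gt_string)  # markers x individuals
  body <- paste(mk$chrom, mk$pos, mk$id, mk$ref, mk$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(ids, seed), body), path)
  invisible(path)
}

#' Read/write annotated exome variant tables
#'
#' VCF dialect: INFO keys `GENE`, `CSQCLASS` (consequence class),
#' `AF_<db>` (per-database population frequency; absent key = absent from
#' that database) and `PRED_<tool>` (`damaging`/`benign`), one GT sample
#' column per pedigree member. The TSV dialect uses columns `freq_<db>`
#' (empty = absent), `pred_<tool>` and `gt_<member>`.
#'
#' @param path input file (`.vcf` or `.tsv`; guessed from extension).
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return a [variant_table()].
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
}

read_variants_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  info_keys <- unique(unlist(lapply(strsplit(unname(fix[, "INFO"]), ";"),
                                    function(x) sub("=.*", "", x))))
  get_info <- function(key) unname(vcfR::extract.info(v, element = key))
  dbs <- sub("^AF_", "", grep("^AF_", info_keys, value = TRUE))
  tools <- sub("^PRED_", "", grep("^PRED_", info_keys, value = TRUE))
  n <- nrow(fix)
  variants <- data.frame(
    id = fix[, "ID"], chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = get_info("GENE"), consequence = get_info("CSQCLASS"),
    stringsAsFactors = FALSE)
  freq <- matrix(NA_real_, n, length(dbs), dimnames = list(NULL, dbs))
  for (d in dbs) freq[, d] <- suppressWarnings(as.numeric(get_info(paste0("AF_", d))))
  pred <- matrix(NA_character_, n, length(tools), dimnames = list(NULL, tools))
  for (tl in tools) pred[, tl] <- get_info(paste0("PRED_", tl))
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- matrix(NA_integer_, n, ncol(gt), dimnames = list(NULL, colnames(gt)))
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (j in seq_len(ncol(gt))) geno[, j] <- codes[gsub("\\|", "/", gt[, j])]
  variant_table(variants, freq, pred, geno)
}

read_variants_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                      na.strings = c("NA", "")),
    error = function(e) stop("malformed variant TSV ", path, ": ",
                             conditionMessage(e)))
  need <- c("id", "chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant TSV ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix), names(df), value = TRUE)
    m <- as.matrix(df[, cols, drop = FALSE])
    colnames(m) <- sub(paste0("^", prefix), "", cols)
    m
  }
  freq <- pick("freq_"); storage.mode(freq) <- "double"
  geno <- pick("gt_"); storage.mode(geno) <- "integer"
  variant_table(df[, need], freq, pick("pred_"), geno)
}

#' @param variants a [variant_table()].
#' @param seed simulation seed for the VCF header.
#' @rdname read_variants
#' @export
write_variants_vcf <- function(variants, path, seed = NULL) {
  vv <- variants$variants
  info <- vapply(seq_len(nrow(vv)), function(i) {
    kv <- c(sprintf("GENE=%s", vv$gene[i]),
            sprintf("CSQCLASS=%s", vv$consequence[i]))
    fq <- variants$freq[i, ]
    kv <- c(kv, sprintf("AF_%s=%.10g", names(fq)[!is.na(fq)], fq[!is.na(fq)]))
    pv <- variants$pred[i, ]
    kv <- c(kv, sprintf("PRED_%s=%s", names(pv)[!is.na(pv)], pv[!is.na(pv)]))
    paste(kv, collapse = ";")
  }, character(1))
  gt <- apply(variants$geno, 1, gt_string)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  else gt <- t(gt)
  body <- paste(vv$chrom, vv$pos, vv$id, vv$ref, vv$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  info_lines <- c(
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQCLASS,Number=1,Type=String,Description="Consequence class">',
    sprintf('##INFO=<ID=AF_%s,Number=1,Type=Float,Description="Population frequency in %s">',
            colnames(variants$freq), colnames(variants$freq)),
    sprintf('##INFO=<ID=PRED_%s,Number=1,Type=String,Description="Verdict of %s">',
            colnames(variants$pred), colnames(variants$pred)))
  writeLines(c(vcf_header(colnames(variants$geno), seed, info_lines), body), path)
  invisible(path)
}

#' @rdname read_variants
#' @export
write_variants_tsv <- function(variants, path) {
  vv <- variants$variants
  fq <- as.data.frame(variants$freq); names(fq) <- paste0("freq_", names(fq))
  pv <- as.data.frame(variants$pred); names(pv) <- paste0("pred_", names(pv))
  gv <- as.data.frame(variants$geno); names(gv) <- paste0("gt_", names(gv))
  data.table::fwrite(cbind(vv, fq, pv, gv), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read/write 6-column pedigree PED files
#'
#' Columns: family, individual, father (0 = founder), mother, sex (1 =
#' male, 2 = female), phenotype (2 = affected, 1 = unaffected).
#'
#' @param path file path.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 6)
  if (length(bad))
    stop("pedigree file ", path, " line ", bad[1], ": expected 6 fields")
  m <- do.call(rbind, parts)
  df <- data.frame(id = m[, 2],
                   father = ifelse(m[, 3] == "0", NA, m[, 3]),
                   mother = ifelse(m[, 4] == "0", NA, m[, 4]),
                   sex = c("male", "female")[as.integer(m[, 5])],
                   affected = m[, 6] == "2",
                   family = m[, 1], stringsAsFactors = FALSE)
  validate_pedigree(df)
}

#' @param pedigree a [pedigree].
#' @rdname read_pedigree
#' @export
write_pedigree <- function(pedigree, path) {
  df <- data.frame(fid = pedigree$family, iid = pedigree$id,
                   pat = ifelse(is.na(pedigree$father), "0", pedigree$father),
                   mat = ifelse(is.na(pedigree$mother), "0", pedigree$mother),
                   sex = ifelse(pedigree$sex == "male", 1L, 2L),
                   pheno = ifelse(pedigree$affected, 2L, 1L))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write interval sets as BED
#'
#' BED uses 0-based half-open coordinates, matching the internal
#' representation directly. An optional `# key=value` comment header
#' carries provenance (e.g. the simulation seed).
#'
#' @param iv an [interval_set()] (or coercible).
#' @param path file path.
#' @param header character vector of comment lines (without `#`).
#' @export
write_bed <- function(iv, path, header = character(0)) {
  iv <- as_interval_set(iv)
  lines <- c(sprintf("# %s", c("coords=0-based half-open", header)),
             sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start), as.integer(iv$end)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(interval_set())
  parts <- strsplit(lines, "\t")
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("BED file ", path, " line ", bad[1], ": expected 3 columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:3))
  interval_set(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]))
}

#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
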