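#' Write a simulated trio cohort to disk
#'
#' Produces the three files a trio analysis consumes: a phased VCF 4.2
#' (children phased with `|`, first allele = maternal origin, second =
#' paternal origin; parents written unphased), a 6-column FAM-style
#' pedigree (family, individual, father, mother, sex, phenotype) and a
#' tab-delimited phenotype table.
#'
#' @param trios a `trio_genotypes` object.
#' @param phenotypes data.frame from [generate_phenotypes()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, a named character vector of the paths written
#'   (`vcf`, `ped`, `pheno`).
#' @export
write_study <- function(trios, phenotypes, dir, prefix = "study") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- nrow(trios$hap_maternal)
  m <- ncol(trios$hap_maternal)
  child_ids <- phenotypes$iid
  mother_ids <- sub("child", "mother", child_ids)
  father_ids <- sub("child", "father", child_ids)

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  phe_path <- file.path(dir, paste0(prefix, ".pheno.tsv"))

  unph <- function(dos) c("0/0", "0/1", "1/1")[dos + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=triopart",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", child_ids, mother_ids, father_ids),
          collapse = "\t")
  )
  body <- character(m)
  v <- trios$variants
  for (j in seq_len(m)) {
    gt_child <- paste0(trios$hap_maternal[, j], "|", trios$hap_paternal[, j])
    gt_mo <- unph(trios$mother[, j])
    gt_fa <- unph(trios$father[, j])
    body[j] <- paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt_child, gt_mo, gt_fa),
                     collapse = "\t")
  }
  writeLines(c(header, body), vcf_path)

  ped <- data.frame(fid = sprintf("fam%05d", seq_len(n)),
                    iid = child_ids, father = father_ids,
                    mother = mother_ids,
                    sex = ifelse(phenotypes$sex == 0, 1L, 2L),
                    pheno = -9L)
  utils::write.table(ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(phenotypes, phe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, ped = ped_path, pheno = phe_path))
}

#' Read a trio study written by [write_study()]
#'
#' Parses the phased VCF, the pedigree and the phenotype table back into
#' a `trio_genotypes` object plus the phenotype data.frame. Child
#' haplotype order is taken as maternal-origin `|` paternal-origin by
#' default; set `origin_order = "paternal-first"` for data phased in the
#' opposite dialect.
#'
#' @param vcf,ped,pheno file paths.
#' @param origin_order `"maternal-first"` (default) or `"paternal-first"`.
#' @return list with `trios` (`trio_genotypes`) and `phenotypes`.
#' @export
read_study <- function(vcf, ped, pheno,
                       origin_order = c("maternal-first", "paternal-first")) {
  origin_order <- match.arg(origin_order)
  lines <- readLines(vcf)
  hdr <- lines[startsWith(lines, "#")]
  cols <- strsplit(hdr[length(hdr)], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]

  pedigree <- utils::read.table(ped, sep = "\t", stringsAsFactors = FALSE,
                                col.names = c("fid", "iid", "father",
                                              "mother", "sex", "pheno"))
  phen <- utils::read.table(pheno, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!all(pedigree$iid %in% samples))
    stop("pedigree children missing from VCF samples: ", vcf)

  ci <- match(pedigree$iid, samples)
  mi <- match(pedigree$mother, samples)
  fi <- match(pedigree$father, samples)
  n <- nrow(pedigree)
  m <- length(body)
  hap_m <- hap_p <- matrix(0L, n, m)
  mo <- fa <- matrix(0L, n, m)
  variants <- data.frame(chrom = character(m), pos = integer(m),
                         ref = character(m), alt = character(m),
                         id = character(m), stringsAsFactors = FALSE)
  dos_from_gt <- function(gt) {
    a <- strsplit(gt, "[/|]")
    vapply(a, function(x) sum(as.integer(x)), integer(1))
  }
  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t")[[1]]
    variants$chrom[j] <- f[1]; variants$pos[j] <- as.integer(f[2])
    variants$id[j] <- f[3]; variants$ref[j] <- f[4]; variants$alt[j] <- f[5]
    gts <- f[-(1:9)]
    cg <- gts[ci]
    ph <- strsplit(cg, "|", fixed = TRUE)
    h1 <- as.integer(vapply(ph, `[`, character(1), 1))
    h2 <- as.integer(vapply(ph, `[`, character(1), 2))
    if (origin_order == "maternal-first") {
      hap_m[, j] <- h1; hap_p[, j] <- h2
    } else {
      hap_m[, j] <- h2; hap_p[, j] <- h1
    }
    mo[, j] <- dos_from_gt(gts[mi])
    fa[, j] <- dos_from_gt(gts[fi])
  }
  trios <- list(hap_maternal = hap_m, hap_paternal = hap_p,
                mother = mo, father = fa,
                freqs = colMeans(hap_m + hap_p) / 2, variants = variants)
  class(trios) <- "trio_genotypes"
  list(trios = trios, phenotypes = phen, pedigree = pedigree)
}

#' Write / read GWAS summary statistics as TSV
#'
#' Column layout: RSID, CHR, POS, EA, OA, EAF, BETA, SE, P, N, N_STUDIES.
#'
#' @param records a `gwas_records` data.frame.
#' @param path file path.
#' @return `read_sumstats` returns the data.frame; `write_sumstats`
#'   returns the path invisibly.
#' @export
write_sumstats <- function(records, path) {
  out <- data.frame(RSID = records$id, CHR = records$chrom,
                    POS = records$pos, EA = records$ea, OA = records$oa,
                    EAF = records$eaf, BETA = records$beta, SE = records$se,
                    P = records$p, N = records$n,
                    N_STUDIES = records$n_studies)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  data.frame(id = x$RSID, chrom = as.character(x$CHR), pos = x$POS,
             ea = x$EA, oa = x$OA, eaf = x$EAF, beta = x$BETA, se = x$SE,
             p = x$P, n = x$N, n_studies = x$N_STUDIES,
             stringsAsFactors = FALSE)
}
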