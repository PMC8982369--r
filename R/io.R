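# Plain-text readers/writers for panels and trait tables, and a minimal CLI.

#' Write a genotype panel as tab-separated text
#'
#' The panel file has a header of `animal_id` followed by SNP ids, one row per
#' animal with dosages (missing as `NA`); the companion map file is a TSV with
#' columns snp_id, chrom, pos_cM.
#'
#' @param panel a `genotype_panel`.
#' @param file panel TSV path.
#' @param map_file SNP map TSV path (default `<file>.map`).
#' @export
write_panel_tsv <- function(panel, file, map_file = paste0(file, ".map")) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(animal_id = rownames(panel$dosages), panel$dosages,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$map, map_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(file, map_file))
}

#' Read a genotype panel written by [write_panel_tsv()]
#'
#' @param file panel TSV path.
#' @param map_file SNP map TSV path.
#' @return a `genotype_panel`.
#' @export
read_panel_tsv <- function(file, map_file = paste0(file, ".map")) {
  df <- utils::read.delim(file, check.names = FALSE)
  map <- utils::read.delim(map_file)
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df$animal_id
  genotype_panel(dos, map)
}

#' Write a trait table as CSV
#'
#' @param traits a trait table.
#' @param file CSV path.
#' @export
write_traits_csv <- function(traits, file) {
  utils::write.csv(traits, file, row.names = FALSE)
  invisible(file)
}

#' Read a trait table written by [write_traits_csv()]
#'
#' @param file CSV path.
#' @param trait_names trait column names (default: columns after the
#'   metadata block animal_id/generation/sex/diet/litter/sire/dam).
#' @return a `trait_table` data.frame.
#' @export
read_traits_csv <- function(file, trait_names = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  meta_cols <- c("animal_id", "generation", "sex", "diet", "litter",
                 "sire", "dam")
  if (is.null(trait_names)) {
    trait_names <- setdiff(names(df), c(meta_cols, grep("_star$", names(df),
                                                        value = TRUE)))
  }
  attr(df, "traits") <- trait_names
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Write a genotype panel as a minimal VCF (unphased GT)
#'
#' Positions are the cM map positions scaled to integer base pairs (1 cM =
#' 1e6 bp, 1-based); REF/ALT are placeholder A/B alleles. Intended for
#' interoperability only.
#'
#' @param panel a `genotype_panel`.
#' @param file output path (plain text).
#' @export
write_panel_vcf <- function(panel, file) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  map <- panel$map
  gt <- c("0/0", "0/1", "1/1")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")), con)
  for (j in seq_len(ncol(dos))) {
    calls <- ifelse(is.na(dos[, j]), "./.", gt[round(dos[, j]) + 1])
    writeLines(paste(c(map$chrom[j], as.integer(round(map$pos_cM[j] * 1e6)) + 1L,
                       map$snp_id[j], "A", "B", ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' Minimal command-line interface
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`simulate --config sim.json --seed S --out DIR` —
#'     simulate founders, population and traits; writes `panel.tsv`,
#'     `panel.tsv.map` and `traits.csv`. The JSON config may hold `founders`
#'     (n_snps, n_chromosomes, maf_range, ...), `design`
#'     (population_design fields), `crossover_rate`, `missing_rate`, and
#'     `traits` (a map of trait name to trait_architecture fields).}
#'   \item{qc}{`qc --in panel.tsv --maf 0.05 --callrate 0.90 --adj-r 0.80
#'     --seed S --out DIR` — run [qc_filter()]; writes the filtered panel and
#'     a JSON + text QC report.}
#'   \item{precorrect}{`precorrect --pheno traits.csv --covariates
#'     diet,generation,litter,sex --out ystar.csv`}
#'   \item{grm}{`grm --panel panel.tsv --kind additive|aa --out G.tsv` —
#'     build the (additive or additive-by-additive) relationship matrix and
#'     write it as TSV with animal ids as header and row names.}
#' }
#'
#' Model fitting, prediction and evaluation are exposed as R functions
#' ([fit_gblup()], [run_gap_scenarios()], [preselect_and_refit()], ...) rather
#' than subcommands.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the output paths.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) stop("usage: <simulate|qc|precorrect> [--key value ...]")
  cmd <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  switch(cmd,
    simulate = {
      cfg <- if (!is.null(opts$config)) jsonlite::read_json(opts$config,
                                                            simplifyVector = TRUE)
             else list()
      seed <- as.integer(opts$seed %||% 1)
      out <- opts$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      fo <- cfg$founders %||% list()
      founders <- simulate_founders(
        n_snps = fo$n_snps %||% 2000, n_chromosomes = fo$n_chromosomes %||% 20,
        maf_range = fo$maf_range %||% c(0.1, 0.5),
        chrom_length_cM = fo$chrom_length_cM %||% 75, seed = seed)
      design <- do.call(population_design, as.list(cfg$design %||% list()))
      pop <- drop_generations(founders, design,
                              crossover_rate = cfg$crossover_rate %||% 1,
                              missing_rate = cfg$missing_rate %||% 0,
                              seed = seed + 1)
      traits <- pop$meta
      tr_cfgs <- cfg$traits %||% list(y = list())
      for (k in seq_along(tr_cfgs)) {
        arch <- do.call(trait_architecture, as.list(tr_cfgs[[k]]))
        ds <- simulate_trait(pop, arch, trait_name = names(tr_cfgs)[k],
                             seed = seed + 1 + k)
        traits[[names(tr_cfgs)[k]]] <- ds$traits[[names(tr_cfgs)[k]]]
      }
      attr(traits, "traits") <- names(tr_cfgs)
      class(traits) <- c("trait_table", "data.frame")
      write_panel_tsv(pop$panel, file.path(out, "panel.tsv"))
      write_traits_csv(traits, file.path(out, "traits.csv"))
      invisible(file.path(out, c("panel.tsv", "traits.csv")))
    },
    qc = {
      panel <- read_panel_tsv(opts[["in"]])
      out <- opts$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      res <- qc_filter(panel,
                       maf_min = as.numeric(opts$maf %||% 0.05),
                       snp_callrate_min = as.numeric(opts$callrate %||% 0.90),
                       adjacent_r_max = as.numeric(opts[["adj-r"]] %||% 0.80),
                       seed = as.integer(opts$seed %||% 1))
      write_panel_tsv(res$panel, file.path(out, "panel_qc.tsv"))
      rep_list <- unclass(res$report)
      jsonlite::write_json(rep_list, file.path(out, "qc_report.json"),
                           auto_unbox = TRUE, digits = NA)
      sink(file.path(out, "qc_report.txt")); print(res$report); sink()
      invisible(file.path(out, c("panel_qc.tsv", "qc_report.json")))
    },
    precorrect = {
      traits <- read_traits_csv(opts$pheno)
      covs <- strsplit(opts$covariates %||% "diet,generation,litter,sex",
                       ",")[[1]]
      traits <- precorrect(traits, covariates = covs)
      utils::write.csv(traits, opts$out %||% "ystar.csv", row.names = FALSE)
      invisible(opts$out %||% "ystar.csv")
    },
    grm = {
      panel <- impute_mean(read_panel_tsv(opts$panel))
      G <- build_g_additive(panel)
      if ((opts$kind %||% "additive") %in% c("aa", "additive_by_additive")) {
        G <- build_g_epistatic(G)
      }
      out <- opts$out %||% "G.tsv"
      df <- data.frame(animal_id = rownames(G), unclass(G), check.names = FALSE)
      utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(out)
    },
    stop("unknown subcommand: ", cmd))
}
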