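# Simulation of a multigenerational outbred population: founder haplotypes,
# recombinant mosaic genomes over unequal non-overlapping generations, and
# complex traits with additive, additive-by-additive and fixed-effect parts.

#' Construct a genotype panel
#'
#' A genotype panel bundles an animals x SNPs dosage matrix (entries 0/1/2 or
#' `NA`) with a SNP map (chromosome and genetic position in cM, positions
#' strictly increasing within chromosome). SNP column order must follow map
#' order; the adjacent-LD pruning rule depends on it.
#'
#' @param dosages numeric matrix, rownames = animal ids, colnames = SNP ids.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos_cM` in the same
#'   order as the columns of `dosages`.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, map) {
  stopifnot(is.matrix(dosages), !is.null(rownames(dosages)),
            !is.null(colnames(dosages)))
  stopifnot(all(c("snp_id", "chrom", "pos_cM") %in% names(map)))
  stopifnot(identical(as.character(map$snp_id), colnames(dosages)))
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) stop("dosage entries must be in [0, 2] or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos_cM[map$chrom == ch]
    if (any(diff(p) <= 0)) stop("map positions must be strictly increasing within chromosome")
  }
  structure(list(dosages = dosages, map = map), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom)),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Population design for the generation-dropping simulator
#'
#' Defaults mirror a diversity-outbred style study design: six non-overlapping
#' generations labelled 4, 5, 7, 8, 9 and 11 with 97, 48, 200, 184, 99 and 197
#' animals, two litters per generation, a 50-50 sex ratio and two diets.
#'
#' @param generation_labels strictly increasing integer labels.
#' @param generation_sizes positive counts, one per label.
#' @param litters_per_generation number of litters within each generation.
#' @param sex_ratio fraction of females.
#' @param diet_levels two diet category labels.
#' @return object of class `population_design`.
#' @export
population_design <- function(generation_labels = c(4, 5, 7, 8, 9, 11),
                              generation_sizes = c(97, 48, 200, 184, 99, 197),
                              litters_per_generation = 2,
                              sex_ratio = 0.5,
                              diet_levels = c("chow", "hf")) {
  stopifnot(length(generation_labels) == length(generation_sizes),
            all(generation_sizes > 0),
            all(diff(generation_labels) > 0),
            litters_per_generation >= 1,
            sex_ratio > 0, sex_ratio < 1,
            length(diet_levels) == 2)
  structure(list(generation_labels = as.integer(generation_labels),
                 generation_sizes = as.integer(generation_sizes),
                 litters_per_generation = as.integer(litters_per_generation),
                 sex_ratio = sex_ratio,
                 diet_levels = diet_levels),
            class = "population_design")
}

#' Simulate founder haplotypes
#'
#' Generates binary haplotypes for `n_founders` inbred founder strains over a
#' SNP map with evenly spaced genetic positions per chromosome. Each SNP's
#' founder-pool allele frequency is drawn from `maf_range` and realised as a
#' count of carrier founders (clamped to keep every SNP segregating among
#' founders).
#'
#' @param n_snps total number of SNPs (split as evenly as possible across
#'   chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param maf_range length-2 numeric in (0, 0.5], lower and upper bound of the
#'   founder minor-allele frequency.
#' @param chrom_length_cM genetic length of each chromosome (default 75 cM,
#'   about the average mouse autosome).
#' @param n_founders number of founder strains (default 8).
#' @param seed integer seed.
#' @return object of class `founder_set` with elements `haplotypes`
#'   (`n_founders` x `n_snps` binary matrix), `map`, `n_founders`.
#' @export
simulate_founders <- function(n_snps, n_chromosomes = 2,
                              maf_range = c(0.1, 0.5),
                              chrom_length_cM = 75,
                              n_founders = 8, seed = 1) {
  stopifnot(n_snps >= n_chromosomes, n_chromosomes >= 1, n_founders >= 2)
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  with_seed(seed, {
    per_chrom <- rep(n_snps %/% n_chromosomes, n_chromosomes)
    extra <- n_snps %% n_chromosomes
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    map <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch) {
      k <- per_chrom[ch]
      data.frame(chrom = ch,
                 pos_cM = seq(0, chrom_length_cM, length.out = max(k, 2))[seq_len(k)])
    }))
    map$snp_id <- sprintf("snp%05d", seq_len(n_snps))
    map <- map[, c("snp_id", "chrom", "pos_cM")]

    f <- stats::runif(n_snps, maf_range[1], maf_range[2])
    k1 <- pmin(pmax(round(n_founders * f), 1L), n_founders - 1L)
    hap <- matrix(0L, n_founders, n_snps,
                  dimnames = list(sprintf("F%d", seq_len(n_founders)), map$snp_id))
    for (j in seq_len(n_snps)) {
      hap[sample.int(n_founders, k1[j]), j] <- 1L
    }
    structure(list(haplotypes = hap, map = map, n_founders = n_founders),
              class = "founder_set")
  })
}

# One recombinant gamete from the two haplotypes of a parent.
# Crossover count per chromosome ~ Poisson(length_Morgan * rate); crossover
# positions uniform on the cM map; the starting haplotype is random.
.gamete <- function(h1, h2, map_split, rate) {
  out <- integer(length(h1))
  for (ms in map_split) {
    idx <- ms$idx
    pos <- ms$pos
    L <- (max(pos) - min(pos)) / 100 # Morgans
    nx <- stats::rpois(1, L * rate)
    cur <- sample.int(2L, 1L)
    if (nx == 0) {
      out[idx] <- if (cur == 1L) h1[idx] else h2[idx]
    } else {
      cuts <- sort(stats::runif(nx, min(pos), max(pos)))
      seg <- findInterval(pos, cuts) # 0..nx segment index
      use1 <- (seg %% 2L == 0L) == (cur == 1L)
      out[idx] <- ifelse(use1, h1[idx], h2[idx])
    }
  }
  out
}

# A founder-mosaic haplotype: segments delimited by Poisson crossovers, each
# segment copied from a uniformly chosen founder strain.
.founder_mosaic <- function(haps, map_split, rate) {
  out <- integer(ncol(haps))
  nf <- nrow(haps)
  for (ms in map_split) {
    idx <- ms$idx
    pos <- ms$pos
    L <- (max(pos) - min(pos)) / 100
    nx <- stats::rpois(1, L * rate)
    if (nx == 0) {
      out[idx] <- haps[sample.int(nf, 1L), idx]
    } else {
      cuts <- sort(stats::runif(nx, min(pos), max(pos)))
      seg <- findInterval(pos, cuts)
      src <- sample.int(nf, nx + 1L, replace = TRUE)
      out[idx] <- haps[cbind(src[seg + 1L], idx)]
    }
  }
  out
}

#' Drop a multigenerational population through random mating
#'
#' Generation one of the design is built as founder-haplotype mosaics; each
#' later generation is produced by random mating of the previous simulated
#' generation (a random sire and a random dam per offspring). Every gamete is a
#' recombinant mosaic with a Poisson crossover count per chromosome
#' (`map length in Morgans * crossover_rate`). Sex, litter and diet are
#' assigned in balanced rotation within each generation so that sexes and diets
#' are close to 50-50 within every generation x litter cell.
#'
#' @param founders a `founder_set`.
#' @param design a `population_design`.
#' @param crossover_rate expected crossovers per Morgan (default 1; 0 gives
#'   intact parental haplotypes).
#' @param missing_rate per-entry Bernoulli genotype missingness injected into
#'   the dosage matrix (default 0).
#' @param seed integer seed.
#' @return object of class `sim_population`: `panel` (genotype_panel, possibly
#'   with missing entries), `meta` (animal_id, generation, sex, diet, litter,
#'   sire, dam), and `haplotypes` (list of two binary matrices; `hap1` is the
#'   sire-derived gamete, `hap2` the dam-derived one).
#' @export
drop_generations <- function(founders, design = population_design(),
                             crossover_rate = 1, missing_rate = 0, seed = 1) {
  stopifnot(inherits(founders, "founder_set"), inherits(design, "population_design"))
  stopifnot(crossover_rate >= 0, missing_rate >= 0, missing_rate < 1)
  map <- founders$map
  m <- nrow(map)
  map_split <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    list(idx = idx, pos = map$pos_cM[idx])
  })
  with_seed(seed, {
    n_total <- sum(design$generation_sizes)
    h1 <- matrix(0L, n_total, m)
    h2 <- matrix(0L, n_total, m)
    meta <- vector("list", length(design$generation_labels))
    row0 <- 0L
    prev_rows <- integer(0)
    prev_meta <- NULL
    for (g in seq_along(design$generation_labels)) {
      lab <- design$generation_labels[g]
      ng <- design$generation_sizes[g]
      ids <- sprintf("g%02d_i%03d", lab, seq_len(ng))
      litter <- rep(seq_len(design$litters_per_generation), length.out = ng)
      # rotate sex within litter, diet within litter x sex
      sex <- character(ng); diet <- character(ng)
      for (l in seq_len(design$litters_per_generation)) {
        li <- which(litter == l)
        sex[li] <- rep(c("F", "M"), length.out = length(li))
        for (s in c("F", "M")) {
          si <- li[sex[li] == s]
          diet[si] <- rep(design$diet_levels, length.out = length(si))
        }
      }
      if (g == 1) {
        sire <- dam <- rep(NA_character_, ng)
        for (i in seq_len(ng)) {
          h1[row0 + i, ] <- .founder_mosaic(founders$haplotypes, map_split, crossover_rate)
          h2[row0 + i, ] <- .founder_mosaic(founders$haplotypes, map_split, crossover_rate)
        }
      } else {
        males <- prev_rows[prev_meta$sex == "M"]
        females <- prev_rows[prev_meta$sex == "F"]
        if (length(males) < 1 || length(females) < 1) {
          stop(sprintf("design error: generation %d has no available sire/dam pair", lab))
        }
        si <- sample(males, ng, replace = TRUE)
        di <- sample(females, ng, replace = TRUE)
        sire <- all_ids[si]
        dam <- all_ids[di]
        for (i in seq_len(ng)) {
          h1[row0 + i, ] <- .gamete(h1[si[i], ], h2[si[i], ], map_split, crossover_rate)
          h2[row0 + i, ] <- .gamete(h1[di[i], ], h2[di[i], ], map_split, crossover_rate)
        }
      }
      meta[[g]] <- data.frame(animal_id = ids, generation = lab, sex = sex,
                              diet = diet, litter = litter, sire = sire, dam = dam,
                              stringsAsFactors = FALSE)
      prev_rows <- row0 + seq_len(ng)
      prev_meta <- meta[[g]]
      row0 <- row0 + ng
      all_ids <- unlist(lapply(meta[seq_len(g)], `[[`, "animal_id"))
    }
    meta <- do.call(rbind, meta)
    dos <- h1 + h2
    storage.mode(dos) <- "double"
    rownames(dos) <- meta$animal_id
    colnames(dos) <- map$snp_id
    rownames(h1) <- rownames(h2) <- meta$animal_id
    colnames(h1) <- colnames(h2) <- map$snp_id
    if (missing_rate > 0) {
      dos[stats::runif(length(dos)) < missing_rate] <- NA_real_
    }
    structure(list(panel = genotype_panel(dos, map), meta = meta,
                   haplotypes = list(hap1 = h1, hap2 = h2)),
              class = "sim_population")
  })
}

#' Trait architecture
#'
#' Describes a complex trait in phenotypic-SD units: number of additive QTL,
#' number of additive-by-additive interacting SNP pairs, the fraction of
#' phenotypic variance that is additive (`h2_additive`) and
#' additive-by-additive (`epistatic_fraction`), and fixed-effect magnitudes per
#' covariate. The genetic part of the phenotype is standardised to unit SD
#' before fixed effects are added.
#'
#' @param n_additive_qtl count of additive QTL.
#' @param n_epistatic_pairs count of interacting SNP pairs (drawn among the
#'   additive QTL when at least two exist, otherwise among all segregating
#'   SNPs).
#' @param h2_additive additive fraction of phenotypic variance.
#' @param epistatic_fraction additive-by-additive fraction.
#' @param fixed_effect_sizes named vector of effect spans, in phenotypic SD, of
#'   the covariates diet, sex, litter and generation.
#' @return object of class `trait_architecture`.
#' @export
trait_architecture <- function(n_additive_qtl = 1000,
                               n_epistatic_pairs = 0,
                               h2_additive = 0.3,
                               epistatic_fraction = 0,
                               fixed_effect_sizes = c(diet = 0.3, sex = 0.3,
                                                      litter = 0.2, generation = 0.2)) {
  stopifnot(n_additive_qtl >= 0, n_epistatic_pairs >= 0)
  if (h2_additive < 0 || h2_additive >= 1 || epistatic_fraction < 0 ||
      epistatic_fraction >= 1 || h2_additive + epistatic_fraction >= 1) {
    stop("parameter error: variance fractions must lie in [0,1) and sum to < 1")
  }
  structure(list(n_additive_qtl = as.integer(n_additive_qtl),
                 n_epistatic_pairs = as.integer(n_epistatic_pairs),
                 h2_additive = h2_additive,
                 epistatic_fraction = epistatic_fraction,
                 fixed_effect_sizes = fixed_effect_sizes),
            class = "trait_architecture")
}

#' Simulate a complex trait on a simulated population
#'
#' Draws additive QTL effects (normal) on centered dosage codes `z = x - 2p`
#' and additive-by-additive pair effects on products of centered codes, then
#' rescales each drawn component so the realised sample variance fraction hits
#' the target exactly; the residual is rescaled to the remaining variance so
#' the genetic-plus-residual phenotype has (approximately) unit SD. Fixed
#' effects of diet, sex, litter and generation are added last as evenly spaced
#' level shifts spanning the configured effect size. The stored components sum
#' to the phenotype exactly.
#'
#' @param pop a `sim_population` from [drop_generations()].
#' @param arch a `trait_architecture`.
#' @param trait_name column name for the phenotype (default "y").
#' @param seed integer seed.
#' @return object of class `sim_dataset`: `panel`, `traits` (a trait table:
#'   meta plus the phenotype column), `components` (per-animal mean, fixed,
#'   additive, epistatic, residual), `realized` variance components,
#'   `qtl` (data.frame snp/beta) and `epi_pairs` (snp1/snp2/gamma), and `arch`.
#' @export
simulate_trait <- function(pop, arch, trait_name = "y", seed = 1) {
  stopifnot(inherits(pop, "sim_population"), inherits(arch, "trait_architecture"))
  dos <- pop$haplotypes$hap1 + pop$haplotypes$hap2 # complete dosages
  storage.mode(dos) <- "double"
  n <- nrow(dos)
  p <- colMeans(dos) / 2
  segregating <- which(p > 0 & p < 1)
  if (arch$n_additive_qtl > length(segregating)) {
    stop("parameter error: n_additive_qtl exceeds the number of segregating SNPs")
  }
  with_seed(seed, {
    zc <- sweep(dos, 2, 2 * p) # centered codes
    a <- numeric(n); qtl <- data.frame(snp = character(0), beta = numeric(0))
    if (arch$n_additive_qtl > 0 && arch$h2_additive > 0) {
      qidx <- sort(sample(segregating, arch$n_additive_qtl))
      beta <- stats::rnorm(arch$n_additive_qtl)
      a_raw <- as.numeric(zc[, qidx, drop = FALSE] %*% beta)
      sc <- sqrt(arch$h2_additive / stats::var(a_raw))
      a <- a_raw * sc
      qtl <- data.frame(snp = colnames(dos)[qidx], beta = beta * sc,
                        stringsAsFactors = FALSE)
    }
    epi <- numeric(n)
    epi_pairs <- data.frame(snp1 = character(0), snp2 = character(0),
                            gamma = numeric(0))
    if (arch$n_epistatic_pairs > 0 && arch$epistatic_fraction > 0) {
      pool <- if (nrow(qtl) >= 2) match(qtl$snp, colnames(dos)) else segregating
      pairs <- matrix(NA_integer_, arch$n_epistatic_pairs, 2)
      seen <- character(0)
      k <- 0L
      while (k < arch$n_epistatic_pairs) {
        pr <- sort(sample(pool, 2))
        key <- paste(pr, collapse = "_")
        if (!(key %in% seen)) {
          k <- k + 1L
          pairs[k, ] <- pr
          seen <- c(seen, key)
        }
      }
      gam <- stats::rnorm(arch$n_epistatic_pairs)
      e_raw <- numeric(n)
      for (k in seq_len(arch$n_epistatic_pairs)) {
        e_raw <- e_raw + gam[k] * zc[, pairs[k, 1]] * zc[, pairs[k, 2]]
      }
      v <- stats::var(e_raw)
      if (v > 0) {
        sc <- sqrt(arch$epistatic_fraction / v)
        epi <- (e_raw - mean(e_raw)) * sc
        epi_pairs <- data.frame(snp1 = colnames(dos)[pairs[, 1]],
                                snp2 = colnames(dos)[pairs[, 2]],
                                gamma = gam * sc, stringsAsFactors = FALSE)
      }
    }
    ve <- 1 - arch$h2_additive - arch$epistatic_fraction
    e_raw <- stats::rnorm(n)
    resid <- if (ve > 0) (e_raw - mean(e_raw)) * sqrt(ve / stats::var(e_raw)) else numeric(n)

    fx <- numeric(n)
    meta <- pop$meta
    for (cv in names(arch$fixed_effect_sizes)) {
      size <- arch$fixed_effect_sizes[[cv]]
      if (is.na(size) || size == 0 || !cv %in% names(meta)) next
      lev <- sort(unique(meta[[cv]]))
      if (length(lev) < 2) next
      eff <- seq(-size / 2, size / 2, length.out = length(lev))
      fx <- fx + eff[match(meta[[cv]], lev)]
    }
    mu <- 0
    y <- mu + fx + a + epi + resid
    traits <- cbind(meta, stats::setNames(data.frame(y), trait_name))
    attr(traits, "traits") <- trait_name
    class(traits) <- c("trait_table", "data.frame")
    comp <- data.frame(animal_id = meta$animal_id, mean = mu, fixed = fx,
                       additive = a, epistatic = epi, residual = resid,
                       stringsAsFactors = FALSE)
    realized <- c(additive = stats::var(a), epistatic = stats::var(epi),
                  residual = stats::var(resid), fixed = stats::var(fx))
    structure(list(panel = pop$panel, meta = meta, traits = traits,
                   components = comp, realized = realized, qtl = qtl,
                   epi_pairs = epi_pairs, arch = arch, trait_name = trait_name,
                   true_additive = stats::setNames(a, meta$animal_id),
                   true_genetic = stats::setNames(a + epi, meta$animal_id)),
              class = "sim_dataset")
  })
}
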