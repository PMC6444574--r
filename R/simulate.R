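# Seeded read simulator with full ground truth. The generator emulates the
# statistical structure of an exosomal small-RNA library: a class mixture
# dominated by miRNA with tsRNAs a few percent of reads; among
# mature-derived tsRNAs, tRNA-5 around 90% with tRNA-3 ~9% and tRNA-i ~1%;
# tRNA-5 fragments concentrated on Gly/Glu/Lys/Val isoacceptors with a
# 32-33 nt length peak; tRNA-3 fragments 16-18 nt; precursor 3'U tRFs
# ending in the poly-U trailer. Every read is logged with its generating
# species, so classification and DE recovery can be scored exactly.

#' Simulation configuration
#'
#' Collects every generator parameter with the package's defaults. The
#' defaults encode the emulated library structure (see the package
#' vignette); each is overridable.
#'
#' @param seed Master seed (mandatory; per-sample seeds are derived from
#'   it deterministically).
#' @param n_reads Reads per sample.
#' @param class_mixture Named probabilities over small-RNA classes; must
#'   sum to 1.
#' @param tsrna_type_probs Named probabilities over
#'   `tRNA-5, tRNA-i, tRNA-3, 3pU-tRF`; must sum to 1.
#' @param isoacceptor_focus Amino acids that dominate tsRNA production.
#' @param focus_weight Total tRNA weight carried by the focus amino acids.
#' @param trna5_end_mean,trna5_end_sd Discretised-normal cut model for the
#'   tRNA-5 3' breakpoint (fragment length), in nt.
#' @param trna3_lengths,trnai_lengths Named length distributions for
#'   tRNA-3 and tRNA-i fragments.
#' @param error_rate Per-base substitution error rate.
#' @param adapter_3p,adapter_5p Adapter sequences; the 3' adapter is
#'   always appended, the 5' adapter only when non-`NULL`.
#' @param read_length Sequencer read length in nt.
#' @param dispersion Per-species gamma abundance noise across samples
#'   (NB-mixture); 0 gives pure multinomial technical replicates.
#' @param abundance_sdlog Log-normal spread of within-type species
#'   abundances.
#' @return A named list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_reads = 50000L,
                              class_mixture = c(
                                miRNA = 0.55, tRNA = 0.05, rRNA = 0.22,
                                snoRNA = 0.08, snRNA = 0.06, piRNA = 0.04
                              ),
                              tsrna_type_probs = c(
                                "tRNA-5" = 0.89, "tRNA-i" = 0.01,
                                "tRNA-3" = 0.09, "3pU-tRF" = 0.01
                              ),
                              isoacceptor_focus = c("Gly", "Glu", "Lys", "Val"),
                              focus_weight = 0.97,
                              trna5_end_mean = 32.5, trna5_end_sd = 1,
                              trna3_lengths = c("16" = 0.30, "17" = 0.35, "18" = 0.35),
                              trnai_lengths = c(
                                "16" = 0.25, "17" = 0.25, "28" = 0.10, "29" = 0.10,
                                "30" = 0.10, "31" = 0.10, "32" = 0.10
                              ),
                              error_rate = 0.001,
                              adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                              adapter_5p = NULL,
                              read_length = 50L,
                              dispersion = 0,
                              abundance_sdlog = 0.5) {
  if (missing(seed)) abort_msg("simulation_config: a seed is mandatory")
  stopifnot(
    abs(sum(class_mixture) - 1) < 1e-8,
    abs(sum(tsrna_type_probs) - 1) < 1e-8,
    abs(sum(trna3_lengths) - 1) < 1e-8,
    abs(sum(trnai_lengths) - 1) < 1e-8,
    error_rate >= 0, dispersion >= 0, read_length >= 16
  )
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a toy tRNA gene set, genome and per-class decoy references
#'
#' Synthetic tRNA genes (spliced body 72-78 nt, anticodon at the canonical
#' spliced position 33-36) on one contig each, with isoacceptor labels
#' drawn from the amino acids observed as tsRNA sources. Every fourth gene
#' carries a 12 nt intron 3' of the anticodon; every fifth is placed on
#' the minus strand. The genomic trailer starts with a TTTT pol-III
#' terminator tract so precursor fragments can end in poly-U. Decoy
#' references are generated for each non-tRNA class. Deterministic under
#' `seed`.
#'
#' @param n_trna_genes Number of tRNA genes (default 12).
#' @param seed Seed.
#' @return List: `genes` (tibble for [build_trna_reference()]), `genome`
#'   (named character), `class_seqs` (per-class named vectors),
#'   `reference` (the built `trna_reference`), `references` (the combined
#'   [reference_table()]).
#' @export
make_toy_references <- function(n_trna_genes = 12L, seed = 1L) {
  set.seed(seed)
  iso_cycle <- list(
    c("Gly", "GCC"), c("Glu", "CTC"), c("Lys", "CTT"), c("Val", "TAC"),
    c("Gly", "TCC"), c("Glu", "TTC"), c("Lys", "TTT"), c("Val", "AAC"),
    c("Ala", "AGC"), c("Asp", "GTC"), c("Leu", "CAA"), c("His", "GTG"),
    c("Ser", "GCT"), c("Phe", "GAA"), c("Arg", "ACG"), c("Cys", "GCA")
  )
  genes <- vector("list", n_trna_genes)
  genome <- character(n_trna_genes)
  contig_names <- sprintf("contig_%02d", seq_len(n_trna_genes))
  for (i in seq_len(n_trna_genes)) {
    iso <- iso_cycle[[(i - 1L) %% length(iso_cycle) + 1L]]
    body_len <- sample(72:78, 1)
    spliced <- random_dna(body_len)
    substr(spliced, 34, 36) <- iso[2]
    has_intron <- i %% 4L == 0L
    if (has_intron) {
      intron <- random_dna(12L)
      gene_seq <- paste0(substr(spliced, 1, 37), intron, substr(spliced, 38, body_len))
      introns <- matrix(c(37L, 49L), ncol = 2)
    } else {
      gene_seq <- spliced
      introns <- matrix(integer(0), ncol = 2)
    }
    glen <- nchar(gene_seq)
    left <- random_dna(60L)
    right <- paste0("TTTT", random_dna(56L))
    sense_window <- paste0(left, gene_seq, right)
    minus <- i %% 5L == 0L
    if (minus) {
      genome[i] <- revcomp(sense_window)
      start <- nchar(sense_window) - 60L - glen
    } else {
      genome[i] <- sense_window
      start <- 60L
    }
    genes[[i]] <- tibble(
      gene_id = sprintf("tRNA-%s-%s-%d-1", iso[1], iso[2], (i - 1L) %/% length(iso_cycle) + 1L),
      chrom = contig_names[i],
      start = start, end = start + glen,
      strand = if (minus) "-" else "+",
      amino_acid = iso[1], anticodon = iso[2],
      anticodon_start = 33L,
      introns = list(introns),
      gene_sequence = gene_seq
    )
  }
  genes <- bind_rows(genes)
  names(genome) <- contig_names
  class_seqs <- list(
    miRNA = setNames(random_dna(rep(21:22, 5)), sprintf("mir-%02d", 1:10)),
    rRNA = setNames(random_dna(c(150L, 150L)), c("rRNA-5.8S", "rRNA-5S")),
    snoRNA = setNames(random_dna(rep(80L, 4)), sprintf("snoRNA-%d", 1:4)),
    snRNA = setNames(random_dna(rep(110L, 3)), sprintf("snRNA-U%d", c(1, 2, 6))),
    piRNA = setNames(random_dna(rep(30L, 6)), sprintf("piRNA-%d", 1:6))
  )
  reference <- build_trna_reference(genes, genome)
  list(
    genes = genes, genome = genome, class_seqs = class_seqs,
    reference = reference,
    references = reference_table(reference, class_seqs)
  )
}

# discretised normal over integer support
disc_normal <- function(support, mean, sd) {
  p <- dnorm(support, mean, sd)
  setNames(p / sum(p), support)
}

#' Build the species pool a library is sampled from
#'
#' Enumerates every emittable species (tRNA fragments per mature/type/cut
#' and decoy-class fragments), assigns each a sampling probability from
#' the configured class mixture, type probabilities, isoacceptor weights
#' and cut models, and perturbs within-type abundances log-normally
#' (normalised so class and type masses stay exact). Uses the current RNG
#' stream; callers seed it.
#'
#' @param config A [simulation_config()].
#' @param refs Output of [make_toy_references()].
#' @return Species tibble: `species_id`, `rna_class`, `ts_class`,
#'   `source_id`, `isoacceptor`, `insert`, `base_prob` (sums to 1).
#' @export
build_species_pool <- function(config, refs) {
  matures <- refs$reference$matures
  precursors <- refs$reference$precursors
  focus <- matures$mature_id[substr(matures$isoacceptor, 1, 3) %in% config$isoacceptor_focus]
  other <- setdiff(matures$mature_id, focus)
  iso_w <- setNames(numeric(nrow(matures)), matures$mature_id)
  if (length(focus) > 0) iso_w[focus] <- config$focus_weight / length(focus)
  if (length(other) > 0) iso_w[other] <- (1 - config$focus_weight) / length(other)

  pool <- list()
  ends5 <- disc_normal(29:36, config$trna5_end_mean, config$trna5_end_sd)
  for (m in seq_len(nrow(matures))) {
    seq <- matures$sequence[m]
    id <- matures$mature_id[m]
    iso <- matures$isoacceptor[m]
    len <- nchar(seq)
    pool[[length(pool) + 1L]] <- tibble(
      rna_class = "tRNA", ts_class = "tRNA-5", source_id = id, isoacceptor = iso,
      insert = substring(seq, 1, as.integer(names(ends5))),
      cut_prob = unname(ends5) * iso_w[id]
    )
    l3 <- as.integer(names(config$trna3_lengths))
    pool[[length(pool) + 1L]] <- tibble(
      rna_class = "tRNA", ts_class = "tRNA-3", source_id = id, isoacceptor = iso,
      insert = substring(seq, len - l3 + 1L, len),
      cut_prob = unname(config$trna3_lengths) * iso_w[id]
    )
    li <- as.integer(names(config$trnai_lengths))
    starts_i <- c(8L, 15L, 22L)
    grid <- expand.grid(start = starts_i, len_i = li)
    ok <- grid$start + grid$len_i <= len - 3L
    grid <- grid[ok, ]
    pool[[length(pool) + 1L]] <- tibble(
      rna_class = "tRNA", ts_class = "tRNA-i", source_id = id, isoacceptor = iso,
      insert = substring(seq, grid$start + 1L, grid$start + grid$len_i),
      cut_prob = unname(config$trnai_lengths[as.character(grid$len_i)]) /
        length(starts_i) * iso_w[id]
    )
  }
  for (p in seq_len(nrow(precursors))) {
    seq <- precursors$sequence[p]
    b <- precursors$mature3_boundary[p]
    grid <- expand.grid(k = c(3L, 4L), L = c(20L, 24L))
    pool[[length(pool) + 1L]] <- tibble(
      rna_class = "tRNA", ts_class = "3pU-tRF",
      source_id = precursors$precursor_id[p],
      isoacceptor = precursors$isoacceptor[p],
      insert = substring(seq, b + grid$k - grid$L + 1L, b + grid$k),
      cut_prob = (1 / nrow(grid)) / nrow(precursors)
    )
  }
  trna <- bind_rows(pool) |>
    distinct(.data$rna_class, .data$ts_class, .data$source_id, .data$insert,
      .keep_all = TRUE
    )
  # renormalise cut mass within each type, then impose the type mixture
  trna <- trna |>
    group_by(.data$ts_class) |>
    mutate(base_prob = .data$cut_prob / sum(.data$cut_prob) *
      config$tsrna_type_probs[.data$ts_class[1]] * config$class_mixture[["tRNA"]]) |>
    ungroup() |>
    select(-"cut_prob")

  decoys <- list()
  for (cls in setdiff(names(config$class_mixture), "tRNA")) {
    seqs <- refs$class_seqs[[cls]]
    if (cls %in% c("miRNA", "piRNA")) {
      frags <- tibble(source_id = names(seqs), insert = unname(seqs))
    } else {
      frags <- bind_rows(lapply(names(seqs), function(nm) {
        s <- seqs[[nm]]
        L <- sample(18:32, 5, replace = TRUE)
        st <- vapply(L, function(l) sample.int(nchar(s) - l + 1L, 1), integer(1))
        tibble(source_id = nm, insert = substring(s, st, st + L - 1L))
      }))
    }
    decoys[[cls]] <- frags |>
      mutate(
        rna_class = cls, ts_class = NA_character_, isoacceptor = NA_character_,
        base_prob = config$class_mixture[[cls]] / nrow(frags)
      )
  }
  species <- bind_rows(trna, bind_rows(decoys))
  # within-type log-normal abundance spread, mass-preserving per stratum
  noise <- exp(rnorm(nrow(species), 0, config$abundance_sdlog))
  species <- species |>
    mutate(.noise = noise) |>
    group_by(.data$rna_class, .data$ts_class) |>
    mutate(base_prob = if (sum(.data$base_prob) == 0) {
      .data$base_prob
    } else {
      .data$base_prob * .data$.noise *
        sum(.data$base_prob) / sum(.data$base_prob * .data$.noise)
    }) |>
    ungroup() |>
    select(-".noise") |>
    mutate(
      base_prob = .data$base_prob / sum(.data$base_prob),
      species_id = sprintf("sp_%04d", dplyr::row_number())
    ) |>
    select(
      "species_id", "rna_class", "ts_class", "source_id",
      "isoacceptor", "insert", "base_prob"
    )
  species
}

# substitute random bases at the given per-read error rate
apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) {
    return(list(seqs = seqs, n_errors = integer(length(seqs))))
  }
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    chars <- strsplit(seqs[i], "")[[1]]
    chars[pos] <- vapply(
      chars[pos],
      function(b) sample(setdiff(DNA_BASES, b), 1),
      character(1)
    )
    seqs[i] <- paste(chars, collapse = "")
  }
  list(seqs = seqs, n_errors = n_err)
}

#' Emit one library from a species pool
#'
#' Draws `n_reads` reads from the pool (multinomial, optionally with
#' per-species gamma abundance noise), applies substitution errors,
#' attaches adapters and truncates to the read length. Uses its own seed,
#' so any single sample is regenerable alone.
#'
#' @param pool Species pool from [build_species_pool()] (optionally with
#'   modified `base_prob`, e.g. DE spiking).
#' @param config A [simulation_config()].
#' @param seed Seed for this library.
#' @param sample_id Sample name used in read ids.
#' @return List: `reads` (tibble `read_id`, `sequence`, `qualities`),
#'   `truth` (per-read tibble with generating class/species/insert),
#'   `species_counts` (pool with the sampled `count` column).
#' @export
emit_library <- function(pool, config, seed, sample_id = "S1") {
  set.seed(seed)
  probs <- pool$base_prob
  if (config$dispersion > 0) {
    shape <- 1 / config$dispersion
    probs <- probs * rgamma(length(probs), shape = shape, rate = shape)
  }
  probs <- probs / sum(probs)
  counts <- rmultinom(1, config$n_reads, probs)[, 1]
  idx <- sample(rep.int(seq_len(nrow(pool)), counts))
  inserts <- pool$insert[idx]
  full <- paste0(config$adapter_5p %||% "", inserts, config$adapter_3p)
  read_seq <- substr(full, 1L, config$read_length)
  err <- apply_errors(read_seq, config$error_rate)
  reads <- tibble(
    read_id = sprintf("%s_read_%07d", sample_id, seq_along(idx)),
    sequence = err$seqs,
    qualities = strrep("F", nchar(err$seqs))
  )
  truth <- tibble(
    read_id = reads$read_id,
    rna_class = pool$rna_class[idx],
    ts_class = pool$ts_class[idx],
    species_id = pool$species_id[idx],
    source_id = pool$source_id[idx],
    isoacceptor = pool$isoacceptor[idx],
    insert = inserts,
    n_errors = err$n_errors
  )
  list(
    reads = reads, truth = truth,
    species_counts = mutate(pool, count = counts)
  )
}

#' Simulate a single small-RNA library with ground truth
#'
#' Builds the species pool under the master seed and emits one library.
#'
#' @inheritParams emit_library
#' @param refs Output of [make_toy_references()].
#' @return As [emit_library()], plus the `pool`.
#' @export
simulate_library <- function(config, refs, sample_id = "S1") {
  set.seed(config$seed)
  pool <- build_species_pool(config, refs)
  out <- emit_library(pool, config, derive_seed(config$seed, 1L), sample_id)
  out$pool <- pool
  out
}

#' Simulate replicate libraries from one generating distribution
#'
#' One species pool, several multinomial draws - the structure of a
#' technical replicate pair.
#'
#' @inheritParams simulate_library
#' @param n_rep Number of replicates.
#' @return Named list of [emit_library()] results (`R1`, `R2`, ...), plus
#'   `pool`.
#' @export
simulate_replicates <- function(config, refs, n_rep = 2L) {
  set.seed(config$seed)
  pool <- build_species_pool(config, refs)
  reps <- lapply(seq_len(n_rep), function(i) {
    emit_library(pool, config, derive_seed(config$seed, i), sprintf("R%d", i))
  })
  names(reps) <- sprintf("R%d", seq_len(n_rep))
  c(reps, list(pool = pool))
}

#' Choose species to spike for a two-group design
#'
#' Picks the most abundant tRNA species and assigns the first `n_up`
#' a positive and the next `n_down` a negative log2 effect.
#'
#' @param pool Species pool.
#' @param n_up,n_down Numbers of up-/down-regulated species (defaults 35
#'   and 11, the structure of the liver-cancer plasma comparison).
#' @param lfc Absolute log2 effect size (default 2).
#' @return Tibble `species_id`, `log2fc`, `direction`.
#' @export
default_de_spec <- function(pool, n_up = 35L, n_down = 11L, lfc = 2) {
  trna <- pool |>
    filter(.data$rna_class == "tRNA") |>
    arrange(dplyr::desc(.data$base_prob))
  if (nrow(trna) < n_up + n_down) {
    abort_msg("pool has only %d tRNA species; cannot spike %d", nrow(trna), n_up + n_down)
  }
  tibble(
    species_id = trna$species_id[seq_len(n_up + n_down)],
    log2fc = rep(c(lfc, -lfc), c(n_up, n_down)),
    direction = rep(c("up", "down"), c(n_up, n_down))
  )
}

#' Simulate a two-group exosomal small-RNA study
#'
#' `n_per_group` control (`N1..`) and case (`T1..`) libraries drawn from
#' one species pool, with `de_spec` species shifted in the case group by
#' their log2 effects, per-sample gamma abundance noise (biological
#' variability) and per-sample seeds derived from the master seed.
#'
#' @inheritParams simulate_library
#' @param n_per_group Samples per group (default 5).
#' @param de_spec Tibble `species_id`, `log2fc` (and optionally
#'   `direction`); `NULL` simulates a null dataset.
#' @param dispersion Per-sample abundance dispersion (default 0.1;
#'   overrides the config value for the group run).
#' @return List: `samples` (named list of [emit_library()] results),
#'   `sample_sheet` (tibble `sample_id`, `group`), `pool`, `de_truth`
#'   (the spike table with `species_key` added).
#' @export
simulate_two_group <- function(config, refs, n_per_group = 5L, de_spec = NULL,
                               dispersion = 0.1) {
  set.seed(config$seed)
  config$dispersion <- dispersion
  pool <- build_species_pool(config, refs)
  case_pool <- pool
  if (!is.null(de_spec)) {
    i <- match(de_spec$species_id, pool$species_id)
    if (anyNA(i)) abort_msg("de_spec references unknown species")
    case_pool$base_prob[i] <- case_pool$base_prob[i] * 2^de_spec$log2fc
    case_pool$base_prob <- case_pool$base_prob / sum(case_pool$base_prob)
  }
  ids <- c(sprintf("N%d", seq_len(n_per_group)), sprintf("T%d", seq_len(n_per_group)))
  groups <- rep(c("control", "case"), each = n_per_group)
  samples <- lapply(seq_along(ids), function(i) {
    p <- if (groups[i] == "case") case_pool else pool
    emit_library(p, config, derive_seed(config$seed, i), ids[i])
  })
  names(samples) <- ids
  de_truth <- NULL
  if (!is.null(de_spec)) {
    meta <- pool[match(de_spec$species_id, pool$species_id), ]
    de_truth <- de_spec |>
      mutate(species_key = species_key(meta$isoacceptor, meta$ts_class, meta$insert))
  }
  list(
    samples = samples,
    sample_sheet = tibble(sample_id = ids, group = groups),
    pool = pool,
    de_truth = de_truth
  )
}

#' Simulate a count matrix directly (no reads)
#'
#' Negative-binomial species-by-sample counts for testing the DE module at
#' scale: species base abundances are log-normal, case-group means are
#' shifted by the spiked log2 effects, and counts are NB with the given
#' dispersion.
#'
#' @param n_species Number of species.
#' @param n_per_group Samples per group.
#' @param de_spec Optional tibble `species` (integer index in
#'   `1:n_species`), `log2fc`.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`).
#' @param lib_size Expected library size per sample.
#' @param seed Seed.
#' @return List: `counts` (long tibble `species_key`, `sample_id`,
#'   `count`), `samples` (sample sheet), `de_truth`.
#' @export
simulate_count_matrix <- function(n_species = 1000L, n_per_group = 5L,
                                  de_spec = NULL, dispersion = 0.1,
                                  lib_size = 1e6, seed = 1L) {
  set.seed(seed)
  base <- exp(rnorm(n_species, log(100), 1))
  base <- base / sum(base)
  lfc <- numeric(n_species)
  if (!is.null(de_spec)) lfc[de_spec$species] <- de_spec$log2fc
  ids <- c(sprintf("N%d", seq_len(n_per_group)), sprintf("T%d", seq_len(n_per_group)))
  groups <- rep(c("control", "case"), each = n_per_group)
  keys <- sprintf("sp_%04d", seq_len(n_species))
  counts <- lapply(seq_along(ids), function(i) {
    mu <- base * if (groups[i] == "case") 2^lfc else 1
    mu <- mu / sum(mu) * lib_size
    tibble(
      species_key = keys, sample_id = ids[i],
      count = rnbinom(n_species, size = 1 / dispersion, mu = mu)
    )
  })
  de_truth <- NULL
  if (!is.null(de_spec)) {
    de_truth <- tibble(
      species_key = keys[de_spec$species], log2fc = de_spec$log2fc,
      direction = ifelse(de_spec$log2fc > 0, "up", "down")
    )
  }
  list(
    counts = bind_rows(counts),
    samples = tibble(sample_id = ids, group = groups),
    de_truth = de_truth
  )
}
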