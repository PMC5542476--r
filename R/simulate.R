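#' Specification of a synthetic expression cohort
#'
#' Describes a case/control cohort with per-gene lognormal baselines (log2
#' scale), independent log2-normal noise, optional latent-factor
#' co-expression blocks, multiplicative case effects planted on designated
#' genes, probe replication, and injected missing and sub-floor values so the
#' QC path is exercised.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_case,n_control Group sizes.
#' @param baseline_mean_range Range (log2) the per-gene baseline means are
#'   drawn from, uniformly.
#' @param baseline_sd Additional per-gene baseline jitter sd (log2).
#' @param noise_sd Per-sample log2 noise sd.
#' @param planted_effects Named numeric vector mapping gene -> linear fold
#'   change added to case samples (all > 0; names must be in the universe).
#' @param coexpression_blocks List of blocks, each a list with elements
#'   `genes` (character) and `loading` (numeric); every sample draws one
#'   standard-normal latent factor per block that is added, scaled by the
#'   loading, to the block's genes.
#' @param missing_rate Probability an entry is set missing.
#' @param probes_per_gene Integer vector the per-gene probe count is sampled
#'   from (default `1:3`).
#' @param probe_noise_sd Probe-level log2 noise sd (default 0.25).
#' @param sub_floor_rate Probability an entry is replaced by a low intensity
#'   below the QC floor (drawn uniformly in log2 `[3, log2(100))`).
#' @param contam_rate,contam_sd Optional heavy-tail contamination: with
#'   probability `contam_rate` an entry receives extra noise of sd
#'   `contam_sd` (default off), exercising the median-versus-mean rationale.
#' @param gene_names Optional explicit gene universe (length `n_genes`).
#' @param class_label Class label given to case samples (controls are
#'   `"healthy"`).
#' @param seed Optional integer seed; identical specs with the same seed give
#'   bit-identical output (Mersenne-Twister / inversion).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 1000, n_case = 20, n_control = 20,
                        baseline_mean_range = c(7, 12), baseline_sd = 0.25,
                        noise_sd = 0.7, planted_effects = NULL,
                        coexpression_blocks = NULL, missing_rate = 0.02,
                        probes_per_gene = 1:3, probe_noise_sd = 0.25,
                        sub_floor_rate = 0.01, contam_rate = 0,
                        contam_sd = 3, gene_names = NULL,
                        class_label = "disease", seed = NULL) {
  stopifnot(n_genes >= 1, n_case >= 1, n_control >= 1,
            length(baseline_mean_range) == 2L,
            baseline_mean_range[1] <= baseline_mean_range[2],
            baseline_sd >= 0, noise_sd >= 0, probe_noise_sd >= 0)
  for (rate in c(missing_rate, sub_floor_rate, contam_rate)) {
    if (rate < 0 || rate > 1) stop("rates must be in [0, 1]")
  }
  if (!is.null(planted_effects)) {
    if (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects)))) {
      stop("`planted_effects` must be a named vector (gene -> fold change)")
    }
    if (any(planted_effects <= 0)) stop("planted fold changes must be > 0")
  }
  if (!is.null(gene_names) && length(gene_names) != n_genes) {
    stop("`gene_names` must have length `n_genes`")
  }
  structure(list(n_genes = n_genes, n_case = n_case, n_control = n_control,
                 baseline_mean_range = baseline_mean_range,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 planted_effects = planted_effects,
                 coexpression_blocks = coexpression_blocks,
                 missing_rate = missing_rate,
                 probes_per_gene = probes_per_gene,
                 probe_noise_sd = probe_noise_sd,
                 sub_floor_rate = sub_floor_rate,
                 contam_rate = contam_rate, contam_sd = contam_sd,
                 gene_names = gene_names, class_label = class_label,
                 seed = seed),
            class = "cohort_spec")
}

## gene x sample log2 matrix: baselines + block factors + noise + class
## effects; `group_effects` maps class label -> named fold-change vector
.sim_expr <- function(genes, sample_classes, baseline, noise_sd,
                      blocks = NULL, group_effects = NULL,
                      contam_rate = 0, contam_sd = 3) {
  n_g <- length(genes)
  n_s <- length(sample_classes)
  e <- baseline + matrix(stats::rnorm(n_g * n_s, 0, noise_sd), n_g, n_s)
  if (contam_rate > 0) {
    hit <- stats::runif(n_g * n_s) < contam_rate
    e[hit] <- e[hit] + stats::rnorm(sum(hit), 0, contam_sd)
  }
  rownames(e) <- genes
  for (blk in blocks %||% list()) {
    bg <- intersect(blk$genes, genes)
    if (!length(bg)) next
    f <- stats::rnorm(n_s)
    e[bg, ] <- e[bg, ] + blk$loading * matrix(f, length(bg), n_s, byrow = TRUE)
  }
  for (cls in names(group_effects %||% list())) {
    eff <- group_effects[[cls]]
    cols <- which(sample_classes == cls)
    if (!length(cols) || !length(eff)) next
    e[names(eff), cols] <- e[names(eff), cols] + log2(eff)
  }
  e
}

#' Generate a synthetic cohort
#'
#' Draws per-gene baselines once, adds latent-factor and independent log2
#' noise, plants the case effects, replicates genes into probes with
#' probe-level noise, and injects sub-floor and missing values at the
#' specified rates.  The returned truth record carries the planted fold
#' changes and block memberships for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return List with elements `probes` (probe-level log2 matrix), `probe_map`
#'   (probe_id -> gene_symbol), `metadata` (sample_id, group, class_label,
#'   sex, age), `truth` (planted effects, blocks, spec).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_optional_seed(spec$seed, {
    genes <- spec$gene_names %||% sprintf("G%04d", seq_len(spec$n_genes))
    pe <- spec$planted_effects
    if (!is.null(pe)) {
      bad <- setdiff(names(pe), genes)
      if (length(bad)) {
        stop("planted gene(s) not in universe: ", paste(bad, collapse = ", "))
      }
    }
    for (blk in spec$coexpression_blocks %||% list()) {
      bad <- setdiff(blk$genes, genes)
      if (length(bad)) {
        stop("block gene(s) not in universe: ", paste(bad, collapse = ", "))
      }
    }
    n <- spec$n_case + spec$n_control
    sample_ids <- sprintf("S%03d", seq_len(n))
    group <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
    baseline <- stats::runif(spec$n_genes, spec$baseline_mean_range[1],
                             spec$baseline_mean_range[2]) +
      stats::rnorm(spec$n_genes, 0, spec$baseline_sd)

    effects <- if (is.null(pe)) NULL else list(case = pe)
    e <- .sim_expr(genes, group, baseline, spec$noise_sd,
                   blocks = spec$coexpression_blocks, group_effects = effects,
                   contam_rate = spec$contam_rate, contam_sd = spec$contam_sd)
    colnames(e) <- sample_ids

    ppg <- spec$probes_per_gene
    k <- if (length(ppg) == 1L) rep(as.integer(ppg), spec$n_genes)
         else sample(ppg, spec$n_genes, replace = TRUE)
    probes <- e[rep(seq_len(spec$n_genes), k), , drop = FALSE]
    if (spec$probe_noise_sd > 0) {
      probes <- probes + matrix(stats::rnorm(length(probes), 0,
                                             spec$probe_noise_sd),
                                nrow(probes), ncol(probes))
    }
    probe_ids <- paste0(rep(genes, k), "_p", sequence(k))
    rownames(probes) <- probe_ids

    if (spec$sub_floor_rate > 0) {
      low <- which(stats::runif(length(probes)) < spec$sub_floor_rate)
      probes[low] <- stats::runif(length(low), 3, log2(100) - 0.05)
    }
    if (spec$missing_rate > 0) {
      probes[stats::runif(length(probes)) < spec$missing_rate] <- NA_real_
    }

    metadata <- data.frame(
      sample_id = sample_ids, group = group,
      class_label = ifelse(group == "case", spec$class_label, "healthy"),
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = round(stats::runif(n, 20, 70)),
      stringsAsFactors = FALSE)

    list(probes = probes,
         probe_map = data.frame(probe_id = probe_ids,
                                gene_symbol = rep(genes, k),
                                stringsAsFactors = FALSE),
         metadata = metadata,
         truth = list(planted_effects = pe,
                      blocks = spec$coexpression_blocks, spec = spec))
  })
}

#' Generate a multi-cohort discovery study
#'
#' Emulates a 20-dataset discovery design.  Each of the 10 virus-response
#' genes is assigned a per-gene mean fold change drawn in `viral_fc_range`
#' (so the gene-level averages over the viral datasets span that range, as
#' printed discovery screens do), and analogously for the bacteria-response
#' genes in `bacterial_fc_range`; per-cohort fold changes jitter around the
#' gene mean by `fc_gene_sd` on the log2 scale.  The `n_viral` viral cohorts
#' plant the virus-response panel, the `n_bacterial` bacterial cohorts the
#' bacteria-response panel.  The `n_mixed` further disease cohorts cycle
#' through a viral-like, a bacterial-like and a dual dysregulation pattern
#' (autoimmune interferon-driven diseases, pyogenic/inflammatory diseases,
#' and tuberculosis-like diseases up-regulating both panels), each planting a
#' random subset (`mixed_subset_sizes` of 10) of the pattern's panel(s) at
#' fold changes in `mixed_fc_range`.  A pool of `n_common` common
#' immune-response genes is
#' additionally planted in each cohort with probability `common_rate` at fold
#' changes in `common_fc_range`, so the frequency-ranked candidate pool
#' resembles a realistic discovery screen.  One latent factor per panel
#' (loading `block_loading`) induces within-panel co-expression in every
#' cohort.
#'
#' Cohorts are gene-level (one probe per gene, no probe noise); individual
#' cohort seeds are derived from `seed` so the whole study is reproducible.
#'
#' @param n_viral,n_bacterial,n_mixed Cohort counts (default 4/4/12).
#' @param n_genes Genes per cohort (>= 55 + panel filler; default 1000).
#' @param n_case,n_control Per-cohort group sizes (default 20/20).
#' @param noise_sd Log2 noise sd (default 0.7).
#' @param viral_fc_range,bacterial_fc_range Ranges the per-gene panel mean
#'   fold changes are drawn from (defaults `c(4.97, 17.42)` and
#'   `c(4.90, 15.91)`).
#' @param fc_gene_sd Per-cohort log2 jitter around the per-gene mean
#'   (default 0.4).
#' @param mixed_fc_range Planted fold-change range in the mixed cohorts
#'   (default `c(4, 12)`).
#' @param mixed_subset_sizes Sizes (of 10) of the panel subset planted in a
#'   mixed cohort (default `8:10`).
#' @param n_common,common_fc_range,common_rate Common immune-response gene
#'   pool: count, fold-change range and per-cohort planting probability.
#' @param block_loading Latent-factor loading on each panel (default 1).
#' @param missing_rate,sub_floor_rate Injection rates per cohort.
#' @param seed Optional master seed.
#' @return An object of class `synthetic_study`: list with `cohorts` (named
#'   list of [generate_cohort()] results), `design` (`viral_ids`,
#'   `bacterial_ids`, `mixed_ids`) and `truth` (`vrg`, `brg`, `common`,
#'   per-cohort planted effects).
#' @export
generate_study <- function(n_viral = 4, n_bacterial = 4, n_mixed = 12,
                           n_genes = 1000, n_case = 20, n_control = 20,
                           noise_sd = 0.7,
                           viral_fc_range = c(4.97, 17.42),
                           bacterial_fc_range = c(4.90, 15.91),
                           fc_gene_sd = 0.4,
                           mixed_fc_range = c(4, 12),
                           mixed_subset_sizes = 8:10,
                           n_common = 35, common_fc_range = c(2.5, 4.5),
                           common_rate = 0.5, block_loading = 1,
                           missing_rate = 0.02, sub_floor_rate = 0.01,
                           seed = NULL) {
  n_total <- n_viral + n_bacterial + n_mixed
  if (n_total == 0L) {
    return(structure(list(cohorts = list(),
                          design = list(viral_ids = character(),
                                        bacterial_ids = character(),
                                        mixed_ids = character()),
                          truth = list()),
                     class = "synthetic_study"))
  }
  vrg <- sprintf("VRG%02d", 1:10)
  brg <- sprintf("BRG%02d", 1:10)
  common <- if (n_common > 0) sprintf("CRG%02d", seq_len(n_common)) else character()
  n_named <- 20L + length(common)
  if (n_genes < n_named + 1L) stop("`n_genes` too small for the panel and common genes")
  gene_names <- c(vrg, brg, common,
                  sprintf("G%04d", seq_len(n_genes - n_named)))
  blocks <- list(list(genes = vrg, loading = block_loading),
                 list(genes = brg, loading = block_loading))

  with_optional_seed(seed, {
    ids <- c(if (n_viral) sprintf("VIR%d", seq_len(n_viral)),
             if (n_bacterial) sprintf("BAC%d", seq_len(n_bacterial)),
             if (n_mixed) sprintf("MIX%02d", seq_len(n_mixed)))
    kind <- rep(c("viral", "bacterial", "mixed"),
                c(n_viral, n_bacterial, n_mixed))
    mixed_pattern <- rep(c("viral", "bacterial", "both"), length.out = n_mixed)

    # per-gene panel means, fixed for the whole study
    mean_v <- stats::setNames(stats::runif(10, viral_fc_range[1],
                                           viral_fc_range[2]), vrg)
    mean_b <- stats::setNames(stats::runif(10, bacterial_fc_range[1],
                                           bacterial_fc_range[2]), brg)
    panel_effects <- function(means) {
      2^stats::rnorm(length(means), log2(means), fc_gene_sd)
    }
    subset_effects <- function(pnl) {
      size <- if (length(mixed_subset_sizes) == 1L) mixed_subset_sizes
              else sample(mixed_subset_sizes, 1L)
      sub <- sample(pnl, size)
      stats::setNames(stats::runif(size, mixed_fc_range[1],
                                   mixed_fc_range[2]), sub)
    }

    cohorts <- stats::setNames(vector("list", n_total), ids)
    planted_by_cohort <- stats::setNames(vector("list", n_total), ids)
    m_i <- 0L
    for (i in seq_len(n_total)) {
      eff <- numeric(0)
      if (kind[i] == "viral") {
        eff <- stats::setNames(panel_effects(mean_v), vrg)
        cls <- "viral"
      } else if (kind[i] == "bacterial") {
        eff <- stats::setNames(panel_effects(mean_b), brg)
        cls <- "bacterial"
      } else {
        m_i <- m_i + 1L
        pat <- mixed_pattern[m_i]
        eff <- switch(pat,
                      viral = subset_effects(vrg),
                      bacterial = subset_effects(brg),
                      both = c(subset_effects(vrg), subset_effects(brg)))
        cls <- paste0("mixed_", pat)
      }
      if (length(common)) {
        hit <- common[stats::runif(length(common)) < common_rate]
        if (length(hit)) {
          eff <- c(eff, stats::setNames(
            stats::runif(length(hit), common_fc_range[1], common_fc_range[2]),
            hit))
        }
      }
      cohort_seed <- sample.int(.Machine$integer.max, 1L)
      spec <- cohort_spec(n_genes = n_genes, n_case = n_case,
                          n_control = n_control, noise_sd = noise_sd,
                          planted_effects = eff,
                          coexpression_blocks = blocks,
                          missing_rate = missing_rate,
                          probes_per_gene = 1L, probe_noise_sd = 0,
                          sub_floor_rate = sub_floor_rate,
                          gene_names = gene_names, class_label = cls,
                          seed = cohort_seed)
      cohorts[[ids[i]]] <- generate_cohort(spec)
      planted_by_cohort[[ids[i]]] <- eff
    }
    structure(list(cohorts = cohorts,
                   design = list(viral_ids = ids[kind == "viral"],
                                 bacterial_ids = ids[kind == "bacterial"],
                                 mixed_ids = ids[kind == "mixed"]),
                   truth = list(vrg = vrg, brg = brg, common = common,
                                mean_fc_vrg = mean_v, mean_fc_brg = mean_b,
                                planted_by_cohort = planted_by_cohort)),
              class = "synthetic_study")
  })
}

#' Generate a mixed viral/bacterial infection cohort
#'
#' One cohort containing viral-infection cases (virus-response genes
#' planted), bacterial-infection cases (bacteria-response genes planted) and
#' healthy controls — the input the (NG_V, NG_B) k-means discrimination
#' consumes.  Gene-level output (no probe replication).
#'
#' @param n_viral,n_bacterial,n_control Group sizes (defaults 40/40/20).
#' @param n_genes Gene universe size (default 100; the first 20 are the
#'   panel).
#' @param noise_sd Log2 noise sd (default 0.7).
#' @param viral_fc_range,bacterial_fc_range Ranges the per-gene panel mean
#'   fold changes are drawn from.
#' @param fc_gene_sd Per-gene log2 jitter around the gene mean (default 0.4).
#' @param block_loading Latent-factor loading per panel (default 1).
#' @param seed Optional integer seed.
#' @return List with `expr` (gene-level log2 matrix), `metadata`
#'   (class_label in viral/bacterial/healthy), `panel` (the true
#'   [gene_panel()]) and `truth` (planted fold changes).
#' @export
generate_infection_cohort <- function(n_viral = 40, n_bacterial = 40,
                                      n_control = 20, n_genes = 100,
                                      noise_sd = 0.7,
                                      viral_fc_range = c(4.97, 17.42),
                                      bacterial_fc_range = c(4.90, 15.91),
                                      fc_gene_sd = 0.4, block_loading = 1,
                                      seed = NULL) {
  stopifnot(n_genes >= 21, n_viral >= 1, n_bacterial >= 1, n_control >= 1)
  vrg <- sprintf("VRG%02d", 1:10)
  brg <- sprintf("BRG%02d", 1:10)
  genes <- c(vrg, brg, sprintf("G%04d", seq_len(n_genes - 20L)))
  with_optional_seed(seed, {
    mv <- stats::runif(10, viral_fc_range[1], viral_fc_range[2])
    mb <- stats::runif(10, bacterial_fc_range[1], bacterial_fc_range[2])
    eff_v <- stats::setNames(2^stats::rnorm(10, log2(mv), fc_gene_sd), vrg)
    eff_b <- stats::setNames(2^stats::rnorm(10, log2(mb), fc_gene_sd), brg)
    n <- n_viral + n_bacterial + n_control
    classes <- rep(c("viral", "bacterial", "healthy"),
                   c(n_viral, n_bacterial, n_control))
    baseline <- stats::runif(n_genes, 7, 12)
    e <- .sim_expr(genes, classes, baseline, noise_sd,
                   blocks = list(list(genes = vrg, loading = block_loading),
                                 list(genes = brg, loading = block_loading)),
                   group_effects = list(viral = eff_v, bacterial = eff_b))
    colnames(e) <- sprintf("S%03d", seq_len(n))
    metadata <- data.frame(
      sample_id = colnames(e),
      group = ifelse(classes == "healthy", "control", "case"),
      class_label = classes, stringsAsFactors = FALSE)
    list(expr = e, metadata = metadata, panel = gene_panel(vrg, brg),
         truth = list(viral_effects = eff_v, bacterial_effects = eff_b))
  })
}

#' Generate a longitudinal panel series with planted events
#'
#' Simulates multi-point sampling of one subject's blood transcriptome:
#' per-gene AR(1) fluctuation around a fixed baseline, plus multiplicative
#' event effects (log2-additive) on the affected panel during each event
#' window `[start, start + duration)`.  The defaults emulate roughly 400 days
#' of biweekly sampling with two strong respiratory-infection events on the
#' virus-response panel and one weak sub-threshold event.
#'
#' @param timepoints Strictly increasing day indices (default
#'   `seq(1, 400, by = 14)`).
#' @param events List of events, each a list with `start`, `duration` (days),
#'   `panel` (`"vrg"` or `"brg"`) and `fold` (linear).  Overlapping windows
#'   on the same panel are an error.
#' @param ar_phi AR(1) coefficient of the per-gene fluctuation (default 0.5).
#' @param ar_sd Stationary sd (log2) of the fluctuation (default 0.3).
#' @param baseline_mean_range Range the per-gene baselines are drawn from.
#' @param seed Optional integer seed.
#' @return List with `series` (genes x timepoints log2 matrix, colnames =
#'   timepoints), `timepoints`, `panel` (the true [gene_panel()]),
#'   `healthy_timepoints` (timepoints outside all event windows) and `truth`
#'   (per-event affected timepoints and folds).
#' @export
generate_longitudinal <- function(timepoints = seq(1, 400, by = 14),
                                  events = list(
                                    list(start = 90, duration = 21,
                                         panel = "vrg", fold = 5),
                                    list(start = 289, duration = 21,
                                         panel = "vrg", fold = 4),
                                    list(start = 350, duration = 14,
                                         panel = "vrg", fold = 1.3)),
                                  ar_phi = 0.5, ar_sd = 0.3,
                                  baseline_mean_range = c(7, 12),
                                  seed = NULL) {
  if (any(diff(timepoints) <= 0)) stop("timepoints must be strictly increasing")
  for (ev in events) {
    stopifnot(all(c("start", "duration", "panel", "fold") %in% names(ev)))
    if (!ev$panel %in% c("vrg", "brg")) stop("event panel must be 'vrg' or 'brg'")
    if (ev$fold <= 0) stop("event fold must be > 0")
  }
  # reject overlapping windows on the same panel
  if (length(events) > 1L) {
    for (i in seq_along(events)) {
      for (j in seq_along(events)) {
        if (i >= j) next
        a <- events[[i]]; b <- events[[j]]
        if (a$panel == b$panel &&
            a$start < b$start + b$duration && b$start < a$start + a$duration) {
          stop("overlapping event windows on the same panel")
        }
      }
    }
  }
  vrg <- sprintf("VRG%02d", 1:10)
  brg <- sprintf("BRG%02d", 1:10)
  genes <- c(vrg, brg)
  n_t <- length(timepoints)
  with_optional_seed(seed, {
    baseline <- stats::runif(length(genes), baseline_mean_range[1],
                             baseline_mean_range[2])
    innov_sd <- ar_sd * sqrt(1 - ar_phi^2)
    series <- t(vapply(seq_along(genes), function(i) {
      baseline[i] + as.numeric(stats::arima.sim(list(ar = ar_phi), n = n_t,
                                                sd = innov_sd))
    }, numeric(n_t)))
    dimnames(series) <- list(genes, as.character(timepoints))
    truth <- vector("list", length(events))
    for (k in seq_along(events)) {
      ev <- events[[k]]
      in_win <- timepoints >= ev$start & timepoints < ev$start + ev$duration
      gset <- if (ev$panel == "vrg") vrg else brg
      series[gset, in_win] <- series[gset, in_win] + log2(ev$fold)
      truth[[k]] <- list(panel = ev$panel, fold = ev$fold,
                         timepoints = timepoints[in_win])
    }
    in_any <- Reduce(`|`, lapply(events, function(ev) {
      timepoints >= ev$start & timepoints < ev$start + ev$duration
    }), accumulate = FALSE, init = rep(FALSE, n_t))
    list(series = series, timepoints = timepoints,
         panel = gene_panel(vrg, brg),
         healthy_timepoints = timepoints[!in_any],
         truth = list(events = truth))
  })
}
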