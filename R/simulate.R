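# Synthetic cohort and raw-feature generator with planted sex effects.
#
# The generator emulates the *shape* of consortium-style working-group
# outputs (per-donor clinical annotation, binary driver events, SNV counts,
# ploidy-adjusted gain/loss segments, subclonal structure, mutation timing,
# signature attribution counts).  No public generative model exists for
# these quantities, so every distributional choice here is a documented
# stand-in; see the package vignette.

.affected <- function(cohort, favoured, scope = "pan-cancer") {
  stopifnot(favoured %in% c("male", "female"))
  cohort$sex == favoured &
    (identical(scope, "pan-cancer") | cohort$subtype == scope)
}

.shiftLogit <- function(p, logOR, affected) {
  stats::plogis(stats::qlogis(p) + logOR * affected)
}

.perSubtype <- function(x, subtypes, what) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(as.double(x), length(subtypes)), subtypes))
  if (!all(subtypes %in% names(x)))
    stop(what, " must be a scalar or named for every subtype")
  stats::setNames(as.double(x[subtypes]), subtypes)
}

#' Assemble the planted-truth table from a simulation configuration
#'
#' One row per configured effect, including nulls.  Magnitudes are recorded
#' on the scale the second-stage models estimate: log odds for binary
#' features, log multipliers for count features (so 0 always encodes a null)
#' and absolute shifts for proportions/fractions.
#'
#' @param config A simulation configuration (see [demoSimulationConfig()]).
#' @return data.frame with columns feature_id, scope, effect_form,
#'   magnitude, favoured_sex.
#' @export
assembleTruth <- function(config) {
  rows <- list()
  add <- function(feature, scope, form, magnitude, favoured) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature_id = feature, scope = scope, effect_form = form,
      magnitude = as.double(magnitude), favoured_sex = favoured,
      stringsAsFactors = FALSE)
  }
  for (ev in config$drivers$events %||% list())
    add(paste0("driver_", ev$id), ev$scope %||% "pan-cancer",
        "log_odds_shift", ev$logOR %||% 0, ev$favoured %||% "male")
  snv <- config$snv
  if (!is.null(snv)) {
    m <- snv$multiplier %||% 1
    for (ctx in c("overall", "coding", "noncoding"))
      add(paste0("density_", ctx), snv$scope %||% "pan-cancer",
          "count_multiplier", log(m), snv$favoured %||% "male")
  }
  for (ef in config$cna$effects %||% list()) {
    add(sprintf("pga_%s_chr%s", ef$call, ef$chrom),
        ef$scope %||% "pan-cancer", "fraction_shift",
        ef$shift %||% 0, ef$favoured %||% "male")
  }
  cl <- config$clonality
  if (!is.null(cl))
    add("polyclonal", cl$scope %||% "pan-cancer", "log_odds_shift",
        cl$logOddsShift %||% 0, cl$favoured %||% "male")
  for (ef in config$timing$effects %||% list())
    add(paste0("truncal_", ef$class), ef$scope %||% "pan-cancer",
        "fraction_shift", ef$shift %||% 0, ef$favoured %||% "male")
  for (ef in config$signatures$effects %||% list()) {
    feat <- sprintf("sig_%s_%s", ef$id,
                    if (identical(ef$on, "presence")) "present" else "activity")
    add(feat, ef$scope %||% "pan-cancer",
        if (identical(ef$on, "presence")) "log_odds_shift" else
          "fraction_shift",
        ef$magnitude %||% 0, ef$favoured %||% "male")
  }
  if (!length(rows))
    return(.emptyDf(feature_id = "character", scope = "character",
                    effect_form = "character", magnitude = "numeric",
                    favoured_sex = "character"))
  do.call(rbind, rows)
}

#' Simulate a cohort annotation table
#'
#' Subtype sample sizes are honoured exactly; everything within a donor
#' (sex, age, ancestry, stage, grade, missingness) is sampled.  Missing
#' values are generated completely at random at the configured rates; sex
#' and subtype are never missing and no sex-specific subtype is emitted.
#'
#' @param config Full simulation configuration, or just its `cohort`
#'   section.  The cohort section lists `subtypes` (each with `name`, `n`,
#'   `maleFraction` and optional `ageMean`/`ageSD`), `ancestryProbs`,
#'   `stageProbs`, `gradeProbs` and a `missing` vector with rates for
#'   age/stage/grade.
#' @param seed Integer master seed.
#' @return list with `cohort` (data.frame) and `truth` (planted effects
#'   echoed from the full configuration; empty if only a cohort section was
#'   supplied).
#' @export
simulateCohort <- function(config, seed = 1L) {
  cc <- config$cohort %||% config
  subs <- cc$subtypes
  if (is.null(subs) || !length(subs)) stop("no subtypes configured")
  cohort <- withSeed(childSeed(seed, .seedStreams[["cohort"]]), {
    pieces <- lapply(subs, function(s) {
      n <- as.integer(s$n)
      if (is.na(n) || n < 1L) stop("subtype n must be >= 1")
      mf <- as.double(s$maleFraction %||% 0.5)
      if (!is.finite(mf) || mf < 0 || mf > 1)
        stop("maleFraction must lie in [0, 1]")
      ageMean <- s$ageMean %||% 60
      ageSD <- s$ageSD %||% 12
      data.frame(
        sex = ifelse(stats::rbinom(n, 1L, mf) == 1L, "male", "female"),
        age = pmax(1, stats::rnorm(n, ageMean, ageSD)),
        subtype = s$name, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, pieces)
    n <- nrow(df)
    df$donor_id <- sprintf("D%05d", seq_len(n))
    ancp <- cc$ancestryProbs %||% c(EUR = 0.72, EAS = 0.18, AFR = 0.10)
    df$ancestry <- names(ancp)[
      sample.int(length(ancp), n, replace = TRUE, prob = ancp)]
    stp <- cc$stageProbs %||% c(I = 0.25, II = 0.35, III = 0.25, IV = 0.15)
    df$stage <- names(stp)[
      sample.int(length(stp), n, replace = TRUE, prob = stp)]
    grp <- cc$gradeProbs %||% c(G1 = 0.3, G2 = 0.45, G3 = 0.25)
    df$grade <- names(grp)[
      sample.int(length(grp), n, replace = TRUE, prob = grp)]
    miss <- cc$missing %||% c(age = 0.05, stage = 0.30, grade = 0.30)
    for (col in c("age", "stage", "grade")) {
      rate <- unname(miss[col])
      if (is.na(rate)) rate <- 0
      df[[col]][stats::runif(n) < rate] <- NA
    }
    df[, c("donor_id", "sex", "age", "ancestry", "subtype", "stage",
           "grade")]
  })
  truth <- if (is.null(config$cohort)) assembleTruth(list()) else
    assembleTruth(config)
  list(cohort = cohort, truth = truth)
}

#' Simulate binary driver-event calls
#'
#' Each event has a baseline mutation probability (applying to the
#' unfavoured sex) and a planted log odds ratio applied to the favoured sex
#' within the configured scope, so the empirical log-OR converges to the
#' planted magnitude as the cohort grows.
#'
#' @param cohort Cohort data.frame.
#' @param config `drivers` section: a list with `events`, each event a list
#'   with `id`, `baseline` in (0,1), `logOR`, `favoured`, `scope`.
#' @param seed Integer master seed.
#' @return Integer 0/1 matrix, donors x events, with dimnames.
#' @export
simulateDriverMutations <- function(cohort, config, seed = 1L) {
  events <- (config$drivers %||% config)$events
  if (is.null(events) || !length(events)) stop("no driver events configured")
  withSeed(childSeed(seed, .seedStreams[["drivers"]]), {
    cols <- lapply(events, function(ev) {
      b <- as.double(ev$baseline)
      if (!is.finite(b) || b <= 0 || b >= 1)
        stop("driver baseline rate must lie strictly in (0, 1)")
      aff <- .affected(cohort, ev$favoured %||% "male",
                       ev$scope %||% "pan-cancer")
      p <- .shiftLogit(b, ev$logOR %||% 0, aff)
      stats::rbinom(nrow(cohort), 1L, p)
    })
    m <- do.call(cbind, cols)
    dimnames(m) <- list(cohort$donor_id,
                        vapply(events, `[[`, character(1), "id"))
    m
  })
}

#' Simulate coding and non-coding SNV counts
#'
#' Donor totals are negative binomial with a per-subtype mean of
#' `ratePerMbp` mutations per megabase over the autosomes; over-dispersion
#' is controlled by `dispersion` (the NB size parameter; large values
#' approach Poisson).  The planted sex effect multiplies the favoured sex's
#' mean, so the male/female median ratio converges to the multiplier.
#' Coding counts are binomial within the total at `codingShare` (defaults
#' to the genome's coding fraction).
#'
#' @param cohort Cohort data.frame.
#' @param genome A \linkS4class{GenomeModel}.
#' @param config `snv` section: `ratePerMbp` (scalar or named by subtype),
#'   `dispersion`, optional `codingShare`, `multiplier`, `favoured`,
#'   `scope`.
#' @param seed Integer master seed.
#' @return data.frame with donor_id, coding_count, noncoding_count.
#' @export
simulateSnvCounts <- function(cohort, genome, config, seed = 1L) {
  sc <- config$snv %||% config
  disp <- as.double(sc$dispersion %||% 2)
  if (!is.finite(disp) || disp <= 0) stop("dispersion must be positive")
  subtypes <- unique(cohort$subtype)
  rates <- .perSubtype(sc$ratePerMbp %||% 1, subtypes, "ratePerMbp")
  if (any(rates <= 0)) stop("ratePerMbp must be positive")
  share <- as.double(sc$codingShare %||%
                       (codingSize(genome) / autosomeSize(genome)))
  if (!is.finite(share) || share <= 0 || share >= 1)
    stop("codingShare must lie strictly in (0, 1)")
  mult <- as.double(sc$multiplier %||% 1)
  if (!is.finite(mult) || mult <= 0) stop("multiplier must be positive")
  aff <- .affected(cohort, sc$favoured %||% "male",
                   sc$scope %||% "pan-cancer")
  mbp <- autosomeSize(genome) / 1e6
  mu <- rates[cohort$subtype] * mbp * ifelse(aff, mult, 1)
  withSeed(childSeed(seed, .seedStreams[["snv"]]), {
    total <- stats::rnbinom(nrow(cohort), size = disp, mu = mu)
    coding <- stats::rbinom(nrow(cohort), total, share)
    data.frame(donor_id = cohort$donor_id, coding_count = coding,
               noncoding_count = total - coding, stringsAsFactors = FALSE)
  })
}

#' Simulate ploidy-adjusted copy number segments
#'
#' Per donor and chromosome, at most one gain and one loss segment are
#' drawn.  A gain occurs with per-chromosome probability `gainProb`
#' (likewise `lossProb`); planted effects add `shift` to the event
#' probability for the favoured sex in the configured scope.  Segment
#' lengths are a Beta-distributed fraction of the chromosome
#' (`lenShape`, defaults Beta(1, 6)) unless `lengthFraction` fixes the
#' fraction (1 = whole chromosome); losses are placed in the larger gap
#' left by the gain so gain and loss intervals are always disjoint.
#'
#' @param cohort Cohort data.frame.
#' @param genome A \linkS4class{GenomeModel}.
#' @param config `cna` section.
#' @param seed Integer master seed.
#' @return A `GRanges` with metadata columns donor_id and call.
#' @export
simulateCnaSegments <- function(cohort, genome, config, seed = 1L) {
  cc <- config$cna %||% config
  cl <- chromLengths(genome)
  chroms <- names(cl)
  perChrom <- function(x, what) {
    if (length(x) == 1L && is.null(names(x)))
      x <- stats::setNames(rep(as.double(x), length(chroms)), chroms)
    x <- as.double(x[chroms]); x[is.na(x)] <- 0
    stopIfNot01(x, what)
    stats::setNames(x, chroms)
  }
  gp <- perChrom(cc$gainProb %||% 0.1, "gainProb")
  lp <- perChrom(cc$lossProb %||% 0.1, "lossProb")
  lenShape <- cc$lenShape %||% c(1, 6)
  fixedFrac <- cc$lengthFraction
  if (!is.null(fixedFrac)) {
    stopIfNot01(fixedFrac, "lengthFraction")
    if (fixedFrac <= 0) stop("lengthFraction must be positive")
  }
  n <- nrow(cohort); C <- length(chroms)
  # probability matrices (donor x chromosome), with planted shifts
  shiftMat <- function(call) {
    m <- matrix(0, n, C, dimnames = list(NULL, chroms))
    for (ef in cc$effects %||% list()) {
      if (!identical(ef$call, call)) next
      aff <- .affected(cohort, ef$favoured %||% "male",
                       ef$scope %||% "pan-cancer")
      m[aff, as.character(ef$chrom)] <-
        m[aff, as.character(ef$chrom)] + (ef$shift %||% 0)
    }
    m
  }
  pGain <- pmin(1, pmax(0, rep(gp, each = n) + shiftMat("gain")))
  pLoss <- pmin(1, pmax(0, rep(lp, each = n) + shiftMat("loss")))
  withSeed(childSeed(seed, .seedStreams[["cna"]]), {
    L <- rep(cl, each = n)                        # donor x chrom grid, bp
    drawLen <- function(k, Lk) {
      frac <- if (is.null(fixedFrac)) stats::rbeta(k, lenShape[1], lenShape[2])
              else rep(fixedFrac, k)
      pmin(Lk, pmax(1, round(frac * Lk)))
    }
    gainEvt <- stats::runif(n * C) < pGain
    gLen <- rep(NA_real_, n * C); gStart <- rep(NA_real_, n * C)
    k <- sum(gainEvt)
    if (k) {
      gLen[gainEvt] <- drawLen(k, L[gainEvt])
      gStart[gainEvt] <-
        floor(stats::runif(k) * (L[gainEvt] - gLen[gainEvt] + 1))
    }
    lossEvt <- stats::runif(n * C) < pLoss
    lLen <- rep(NA_real_, n * C); lStart <- rep(NA_real_, n * C)
    k <- sum(lossEvt)
    if (k) {
      idx <- which(lossEvt)
      want <- drawLen(k, L[idx])
      hasG <- gainEvt[idx]
      gapLeft <- ifelse(hasG, gStart[idx], L[idx])
      gapRight <- ifelse(hasG, L[idx] - gStart[idx] - gLen[idx], 0)
      useLeft <- gapLeft >= gapRight
      avail <- pmax(gapLeft, gapRight)
      len <- pmin(want, avail)
      ok <- len >= 1
      off <- ifelse(useLeft, 0, gStart[idx] + gLen[idx])
      st <- off + floor(stats::runif(k) * (avail - len + 1))
      lLen[idx[ok]] <- len[ok]
      lStart[idx[ok]] <- st[ok]
    }
    mk <- function(startVec, lenVec, call) {
      sel <- which(!is.na(startVec))
      if (!length(sel)) return(NULL)
      data.frame(
        donor_id = cohort$donor_id[(sel - 1L) %% n + 1L],
        chrom = chroms[(sel - 1L) %/% n + 1L],
        start = startVec[sel], len = lenVec[sel], call = call,
        stringsAsFactors = FALSE)
    }
    segs <- rbind(mk(gStart, gLen, "gain"), mk(lStart, lLen, "loss"))
    si <- seqinfo(geneCatalogue(genome))
    if (is.null(segs))
      return(GRanges(seqinfo = si))
    gr <- GRanges(segs$chrom,
                  IRanges(start = segs$start + 1L,
                          width = segs$len),
                  donor_id = segs$donor_id, call = segs$call, seqinfo = si)
    sort(gr)
  })
}

#' Simulate subclonal structure and mutation timing
#'
#' Polyclonality is Bernoulli per donor (per-subtype probability, planted
#' log-odds shift for the favoured sex); polyclonal donors get
#' `2 + Poisson(clusterLambda)` subclonal clusters.  Per variant class
#' (SNV/indel/SV), totals are negative binomial and each polyclonal donor's
#' truncal fraction is Beta-distributed around the class parameter
#' `truncal` (planted shifts move it for the favoured sex); monoclonal
#' donors are entirely truncal, so they never carry subclonal variants.
#'
#' @param cohort Cohort data.frame.
#' @param config List with `clonality` and `timing` sections (or a full
#'   simulation configuration).
#' @param seed Integer master seed.
#' @return list with `clonality` and `timing` data.frames.
#' @export
simulateClonalityTiming <- function(cohort, config, seed = 1L) {
  cc <- config$clonality
  tc <- config$timing
  if (is.null(cc) && is.null(tc))
    stop("config must contain 'clonality' and/or 'timing' sections")
  n <- nrow(cohort)
  subtypes <- unique(cohort$subtype)
  withSeed(childSeed(seed, .seedStreams[["clonality"]]), {
    poly <- rep(FALSE, n)
    clonality <- NULL
    if (!is.null(cc)) {
      pp <- .perSubtype(cc$polyProb %||% 0.5, subtypes, "polyProb")
      stopIfNot01(pp, "polyProb")
      p <- unname(pp[cohort$subtype])
      shift <- cc$logOddsShift %||% 0
      if (shift != 0) {
        aff <- .affected(cohort, cc$favoured %||% "male",
                         cc$scope %||% "pan-cancer")
        p <- .shiftLogit(p, shift, aff)
      }
      poly <- stats::runif(n) < p
      nClusters <- ifelse(poly, 2L + stats::rpois(n, cc$clusterLambda %||%
                                                    0.6), 1L)
      clonality <- data.frame(donor_id = cohort$donor_id,
                              n_clusters = as.integer(nClusters),
                              stringsAsFactors = FALSE)
    }
    timing <- NULL
    if (!is.null(tc)) {
      shifts <- list()
      for (ef in tc$effects %||% list()) shifts[[ef$class]] <- ef
      pieces <- lapply(names(tc$classes), function(clName) {
        cls <- tc$classes[[clName]]
        theta <- as.double(cls$truncal %||% 0.85)
        stopIfNot01(theta, "truncal parameter")
        kappa <- as.double(cls$kappa %||% 12)
        tot <- stats::rnbinom(n, size = cls$totalDisp %||% 2,
                              mu = cls$totalMean %||% 100)
        th <- rep(theta, n)
        ef <- shifts[[clName]]
        if (!is.null(ef)) {
          aff <- .affected(cohort, ef$favoured %||% "male",
                           ef$scope %||% "pan-cancer")
          th <- pmin(1, pmax(0, th + (ef$shift %||% 0) * aff))
        }
        frac <- ifelse(th >= 1, 1,
                ifelse(th <= 0, 0,
                       stats::rbeta(n, th * kappa, (1 - th) * kappa)))
        if (!is.null(cc)) frac[!poly] <- 1  # monoclonal: entirely truncal
        tr <- stats::rbinom(n, tot, frac)
        data.frame(donor_id = cohort$donor_id, variant_class = clName,
                   n_truncal = tr, n_subclonal = tot - tr,
                   stringsAsFactors = FALSE)
      })
      timing <- do.call(rbind, pieces)
    }
    list(clonality = clonality, timing = timing)
  })
}

#' Simulate mutational-signature attribution counts
#'
#' For each signature class (SBS/DBS/ID) a donor draws a negative binomial
#' class total, a Bernoulli presence indicator per signature (baseline
#' probability with planted log-odds shifts), and Dirichlet-multinomial
#' attributed counts over the present signatures, so per-donor counts
#' within a class always sum to the class total.  Planted activity effects
#' shift the favoured sex's expected attributed fraction for one signature.
#' A donor with no present signature in a class is given a class total of
#' zero (an all-zero row, excluded downstream).
#'
#' @param cohort Cohort data.frame.
#' @param config `signatures` section: `catalogue` (data.frame with id,
#'   class, presence, weight), `classTotals` (list class -> c(mean, disp)),
#'   `concentration` (Dirichlet concentration, default 60) and `effects`.
#' @param seed Integer master seed.
#' @return list with `counts` (integer matrix donors x signatures) and
#'   `classes` (named character).
#' @export
simulateSignatures <- function(cohort, config, seed = 1L) {
  sc <- config$signatures %||% config
  cat <- sc$catalogue
  if (is.null(cat) || !nrow(cat)) stop("no signature catalogue configured")
  stopifnot(all(c("id", "class", "presence", "weight") %in% names(cat)))
  if (any(cat$weight < 0) || any(tapply(cat$weight, cat$class, sum) <= 0))
    stop("signature weights do not form a valid composition")
  stopIfNot01(cat$presence, "presence probability")
  n <- nrow(cohort)
  conc <- sc$concentration %||% 60
  withSeed(childSeed(seed, .seedStreams[["signatures"]]), {
    counts <- matrix(0L, n, nrow(cat),
                     dimnames = list(cohort$donor_id, cat$id))
    presEff <- list(); actEff <- list()
    for (ef in sc$effects %||% list()) {
      if (identical(ef$on, "presence")) presEff[[ef$id]] <- ef
      else actEff[[ef$id]] <- ef
    }
    pres <- matrix(FALSE, n, nrow(cat))
    for (j in seq_len(nrow(cat))) {
      p <- rep(cat$presence[j], n)
      ef <- presEff[[cat$id[j]]]
      if (!is.null(ef)) {
        aff <- .affected(cohort, ef$favoured %||% "male",
                         ef$scope %||% "pan-cancer")
        p <- .shiftLogit(p, ef$magnitude %||% 0, aff)
      }
      pres[, j] <- stats::runif(n) < p
    }
    for (clName in unique(cat$class)) {
      jj <- which(cat$class == clName)
      ct <- sc$classTotals[[clName]] %||% c(mean = 1000, disp = 1.5)
      tot <- stats::rnbinom(n, size = unname(ct[2]), mu = unname(ct[1]))
      tot[rowSums(pres[, jj, drop = FALSE]) == 0L] <- 0L
      w <- cat$weight[jj]
      affAct <- matrix(0, n, length(jj))
      for (k in seq_along(jj)) {
        ef <- actEff[[cat$id[jj[k]]]]
        if (!is.null(ef))
          affAct[, k] <- (ef$magnitude %||% 0) *
            .affected(cohort, ef$favoured %||% "male",
                      ef$scope %||% "pan-cancer")
      }
      for (i in which(tot > 0L)) {
        act <- which(pres[i, jj])
        p <- w[act] / sum(w[act])
        sh <- affAct[i, act]
        if (any(sh != 0)) {
          pNew <- pmin(0.999, pmax(0.001, p + sh))
          rest <- sh == 0
          if (any(rest) && sum(p[rest]) > 0)
            pNew[rest] <- p[rest] * (1 - sum(pNew[!rest])) / sum(p[rest])
          p <- pNew / sum(pNew)
        }
        g <- stats::rgamma(length(act), shape = conc * p)
        if (sum(g) <= 0) g <- p
        counts[i, jj[act]] <- as.integer(
          stats::rmultinom(1L, tot[i], g / sum(g)))
      }
    }
    list(counts = counts,
         classes = stats::setNames(cat$class, cat$id))
  })
}

#' Simulate a complete dataset
#'
#' Orchestrates the component simulators; each draws its own child seed via
#' [childSeed()], so a component's output depends only on `(config, seed)`
#' and not on which other components are configured.
#'
#' @param config Simulation configuration; sections `genome` and `cohort`
#'   are required, the component sections (`drivers`, `snv`, `cna`,
#'   `clonality`, `timing`, `signatures`) are optional.
#' @param seed Integer master seed.
#' @return A \linkS4class{SexBiasDataset}.
#' @export
#' @examples
#' ds <- simulateDataset(demoSimulationConfig(nPerSubtype = 40), seed = 7)
#' ds
simulateDataset <- function(config, seed = 1L) {
  genome <- makeGenomeModel(config$genome %||% defaultGenomeConfig(), seed)
  coh <- simulateCohort(config, seed)
  cohort <- coh$cohort
  emptyMat <- matrix(integer(), 0L, 0L)
  drivers <- if (!is.null(config$drivers))
    simulateDriverMutations(cohort, config, seed) else emptyMat
  snv <- if (!is.null(config$snv))
    simulateSnvCounts(cohort, genome, config, seed) else
      .emptyDf(donor_id = "character", coding_count = "integer",
               noncoding_count = "integer")
  segments <- if (!is.null(config$cna))
    simulateCnaSegments(cohort, genome, config, seed) else
      GRanges(seqinfo = seqinfo(geneCatalogue(genome)))
  clonality <- .emptyDf(donor_id = "character", n_clusters = "integer")
  timing <- .emptyDf(donor_id = "character", variant_class = "character",
                     n_truncal = "integer", n_subclonal = "integer")
  if (!is.null(config$clonality) || !is.null(config$timing)) {
    ct <- simulateClonalityTiming(cohort, config, seed)
    if (!is.null(ct$clonality)) clonality <- ct$clonality
    if (!is.null(ct$timing)) timing <- ct$timing
  }
  sigs <- emptyMat; sigClass <- character()
  if (!is.null(config$signatures)) {
    sg <- simulateSignatures(cohort, config, seed)
    sigs <- sg$counts; sigClass <- sg$classes
  }
  new("SexBiasDataset", cohort = cohort, drivers = drivers, snv = snv,
      segments = segments, clonality = clonality, timing = timing,
      signatures = sigs, signatureClass = sigClass, genome = genome,
      truth = coh$truth)
}
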