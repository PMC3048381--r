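#' Background distribution specification for synthetic rate tables
#'
#' Defaults are a stylised genome-scale free-ratio run for a mammal-like
#' branch: right-skewed gamma rates with mean dS = 0.1 (shape 3, rate 30)
#' and mean dN = 0.02 (shape 1.5, rate 75), giving omega = dN/dS mostly
#' below 1 (purifying selection) with a long right tail. dS shape 3 keeps
#' 1/dS square-integrable so the sample standard deviation of omega, used by
#' [plant_modules()] to scale effects, is stable.
#'
#' @param dS,dN,dS_ancestral,dN_ancestral named numeric vectors
#'   `c(shape, rate)` of gamma parameters.
#' @return A `background_spec` list.
#' @export
background_spec <- function(dS = c(shape = 3, rate = 30),
                            dN = c(shape = 1.5, rate = 75),
                            dS_ancestral = dS, dN_ancestral = dN) {
  spec <- list(dS = dS, dN = dN,
               dS_ancestral = dS_ancestral, dN_ancestral = dN_ancestral)
  for (nm in names(spec)) {
    v <- spec[[nm]]
    if (!all(c("shape", "rate") %in% names(v)) || any(v[c("shape", "rate")] <= 0)) {
      stop_config("background_spec$", nm, " needs positive shape and rate")
    }
  }
  structure(spec, class = "background_spec")
}

#' Simulate a genome-scale rate table
#'
#' Draws per-gene dS and dN from right-skewed gamma distributions, derives
#' omega = dN/dS, and simulates an independent ancestral branch the same way
#' so that delta_omega = omega - omega_ancestral is exercised. Deterministic
#' given the seed.
#'
#' @param n_genes number of genes (>= 100 for realistic use; smaller tables
#'   are allowed for toys).
#' @param spec a [background_spec()].
#' @param seed integer seed.
#' @param branch branch id recorded on every record.
#' @return A [rate_table][read_rate_table].
#' @examples
#' rt <- simulate_rates(1000, seed = 42)
#' summary(rt$omega)
#' @export
simulate_rates <- function(n_genes, spec = background_spec(), seed = 1L,
                           branch = "focal") {
  if (!inherits(spec, "background_spec")) spec <- do.call(background_spec, spec)
  n_genes <- as.integer(n_genes)
  if (n_genes < 2L) stop_config("n_genes must be >= 2")
  with_local_seed(seed, {
    draw <- function(par) stats::rgamma(n_genes, shape = par[["shape"]],
                                        rate = par[["rate"]])
    dS <- draw(spec$dS)
    dN <- draw(spec$dN)
    dS_a <- draw(spec$dS_ancestral)
    dN_a <- draw(spec$dN_ancestral)
    omega <- dN / dS
    omega_a <- dN_a / dS_a
    new_rate_table(data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      branch_id = branch,
      dS = dS, dN = dN, omega = omega,
      omega_ancestral = omega_a,
      delta_omega = omega - omega_a,
      aln_length_bp = NA_real_,
      stringsAsFactors = FALSE
    ))
  })
}

#' Random annotation map over a gene universe
#'
#' Builds terms of given sizes by sampling genes uniformly without
#' replacement (independently per term), e.g. for null calibration runs.
#'
#' @param universe character vector of gene ids.
#' @param sizes integer vector of term sizes; one term per element.
#' @param seed integer seed.
#' @param prefix term-id prefix.
#' @return An [annotation_map()].
#' @export
random_annotation <- function(universe, sizes, seed = 1L, prefix = "T") {
  universe <- as.character(universe)
  if (any(sizes > length(universe))) {
    stop_validation("term size exceeds the universe")
  }
  with_local_seed(seed, {
    assignments <- lapply(seq_along(sizes), function(i) sample(universe, sizes[i]))
    names(assignments) <- sprintf("%s%04d", prefix, seq_along(sizes))
    annotation_map(assignments, universe = universe)
  })
}

#' Ground truth for planted modules
#'
#' @param directions character vector of `"SH"` / `"SL"` per planted term.
#' @param effects rank-shift effect sizes, in units of the background
#'   standard deviation of the ranking variable.
#' @param sizes genes per planted term.
#' @param n_controls number of negative-control terms (random membership,
#'   sizes resampled from `sizes`).
#' @param seed integer seed used for membership sampling.
#' @return A `synthetic_truth` object with a `planted` data.frame.
#' @export
synthetic_truth <- function(directions, effects, sizes, n_controls = length(sizes),
                            seed = 1L) {
  stopifnot(length(directions) == length(effects),
            length(effects) == length(sizes))
  if (!all(directions %in% c("SH", "SL"))) {
    stop_config("directions must be 'SH' or 'SL'")
  }
  if (!all(is.finite(effects))) stop_config("effects must be finite")
  planted <- data.frame(
    term_id = sprintf("planted%03d", seq_along(sizes)),
    direction = directions, effect = effects, size = as.integer(sizes),
    stringsAsFactors = FALSE
  )
  structure(list(planted = planted, n_controls = as.integer(n_controls),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Plant rank-shifted modules into a rate table
#'
#' For each planted term, a disjoint set of member genes is sampled and the
#' ranking variable of those genes is shifted by
#' `effect * sd(background variable)` - upward for SH, downward for SL (the
#' minimal mechanism producing the rank skew the segmentation test detects).
#' Downward shifts are clamped at 0 for non-negative variables, which leaves
#' the affected genes tied at the bottom of the ranking. Dependent columns
#' are recomputed so the table stays internally consistent (shifting omega
#' rescales dN = omega * dS; shifting dS or dN rederives omega; shifting
#' delta_omega moves omega with the ancestral value fixed). Negative-control
#' terms with random membership and sizes resampled from the planted sizes
#' are added so term size is not a confound in recovery reports.
#'
#' @param table a [rate_table][read_rate_table] (single branch).
#' @param truth a [synthetic_truth()].
#' @param variable the ranking variable the effect acts on.
#' @return List with `table` (modified), `map` (an [annotation_map()] of
#'   planted plus control terms) and `truth` (with membership attached).
#' @export
plant_modules <- function(table, truth,
                          variable = c("omega", "dS", "dN", "delta_omega")) {
  variable <- match.arg(variable)
  stopifnot(inherits(truth, "synthetic_truth"))
  df <- as.data.frame(table)
  planted <- truth$planted
  if (sum(planted$size) > nrow(df)) {
    stop_validation("total planted genes (", sum(planted$size),
                    ") exceed the number of genes (", nrow(df), ")")
  }
  base <- switch(variable,
                 omega = df$omega, dS = df$dS, dN = df$dN,
                 delta_omega = df$delta_omega)
  if (anyNA(base)) stop_validation("ranking variable has missing values")
  sd_bg <- stats::sd(base)

  with_local_seed(truth$seed, {
    pool <- sample(df$gene_id) # disjoint planted membership
    offset <- 0L
    members <- vector("list", nrow(planted))
    shifted <- base
    for (i in seq_len(nrow(planted))) {
      g <- pool[(offset + 1L):(offset + planted$size[i])]
      offset <- offset + planted$size[i]
      members[[i]] <- sort(g)
      sgn <- if (planted$direction[i] == "SH") 1 else -1
      idx <- match(g, df$gene_id)
      shifted[idx] <- shifted[idx] + sgn * planted$effect[i] * sd_bg
    }
    if (variable != "delta_omega") shifted <- pmax(shifted, 0)

    if (variable == "omega") {
      df$omega <- shifted
      df$dN <- df$omega * df$dS
    } else if (variable == "dS") {
      df$dS <- shifted
      df$omega <- ifelse(df$dS > 0, df$dN / df$dS, NA_real_)
    } else if (variable == "dN") {
      df$dN <- shifted
      df$omega <- ifelse(df$dS > 0, df$dN / df$dS, NA_real_)
    } else { # delta_omega: move omega, ancestor fixed
      df$omega <- df$omega_ancestral + shifted
      df$omega <- pmax(df$omega, 0)
      df$dN <- df$omega * df$dS
    }
    df$delta_omega <- df$omega - df$omega_ancestral

    ctrl_sizes <- sample(planted$size, truth$n_controls, replace = TRUE)
    controls <- lapply(ctrl_sizes, function(s) sample(df$gene_id, s))
    names(controls) <- sprintf("control%03d", seq_along(controls))
    assignments <- c(stats::setNames(members, planted$term_id), controls)
    truth$membership <- stats::setNames(members, planted$term_id)
    list(table = new_rate_table(df),
         map = annotation_map(assignments, universe = df$gene_id),
         truth = truth)
  })
}

#' Recovery report for planted modules
#'
#' @param calls per-term verdicts (the `calls` component of a [gssa()]
#'   result) computed on the planted map.
#' @param truth the [synthetic_truth()] used to plant.
#' @return List with `sensitivity_SH`, `sensitivity_SL` (fraction of planted
#'   terms whose verdict matches their direction; `NA` if none planted in
#'   that direction), `direction_accuracy` (among detected planted terms),
#'   `fdp` (non-planted non-NS terms over all non-NS terms; `NA` when no
#'   term is called), and the underlying counts.
#' @export
recovery_report <- function(calls, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  planted <- truth$planted
  idx <- match(planted$term_id, calls$term_id)
  if (anyNA(idx)) stop_validation("calls are missing planted term(s)")
  verdicts <- calls$verdict[idx]
  sens_dir <- function(dir) {
    sel <- planted$direction == dir
    if (!any(sel)) return(NA_real_)
    mean(verdicts[sel] == dir)
  }
  detected <- verdicts != "NS"
  pos <- calls$verdict != "NS"
  n_pos <- sum(pos)
  n_false <- sum(pos & !(calls$term_id %in% planted$term_id))
  list(
    sensitivity_SH = sens_dir("SH"),
    sensitivity_SL = sens_dir("SL"),
    direction_accuracy = if (any(detected))
      mean(verdicts[detected] == planted$direction[detected]) else NA_real_,
    fdp = if (n_pos > 0) n_false / n_pos else NA_real_,
    n_planted = nrow(planted), n_detected = sum(detected),
    n_called = n_pos, n_false_calls = n_false
  )
}
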