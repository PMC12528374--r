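#' Convert integrin density to scaled focal-adhesion length
#'
#' Linear scaling that equates an integrin density of 84.1 arb. units with a
#' focal-adhesion length of 1 micrometre; the same factor is applied to all
#' density values.
#'
#' @param integrin_density integrin density in arbitrary units, `>= 0`;
#'   vectorised.
#' @return Focal-adhesion length(s) in micrometres.
#' @examples
#' scale_to_fa_length(84.1)   # 1
#' scale_to_fa_length(168.2)  # 2
#' @export
scale_to_fa_length <- function(integrin_density) {
  if (any(integrin_density < 0))
    stop("integrin density must be non-negative")
  integrin_density / 84.1
}

#' Summarise one condition over replicate simulations
#'
#' Mean and standard deviation, across replicates, of the steady-state
#' scaled focal-adhesion length and retrograde flow speed.
#'
#' @param results a list of [run_simulation] results (`>= 2`).
#' @param condition optional condition label to attach.
#' @return An object of class `condition_summary`: a one-row data.frame with
#'   columns `condition`, `fa_mean`, `fa_sd`, `flow_mean`, `flow_sd`,
#'   `n_replicates`, carrying the per-replicate values in attribute
#'   `"replicates"`.
#' @export
summarise_condition <- function(results, condition = NA_character_) {
  if (length(results) < 2)
    stop("at least 2 replicate simulations required")
  fa <- vapply(results, function(r)
    scale_to_fa_length(r$summary$integrin_density), numeric(1))
  flow <- vapply(results, function(r) r$summary$flow, numeric(1))
  out <- data.frame(condition = condition,
                    fa_mean = mean(fa), fa_sd = sd(fa),
                    flow_mean = mean(flow), flow_sd = sd(flow),
                    n_replicates = length(results),
                    stringsAsFactors = FALSE)
  attr(out, "replicates") <- data.frame(condition = condition,
                                        replicate = seq_along(fa),
                                        fa_length = fa, flow = flow,
                                        stringsAsFactors = FALSE)
  class(out) <- c("condition_summary", class(out))
  out
}

# Deterministic per-replicate seed from (root seed, condition index,
# replicate index); stays below 2^31.
replicate_seed <- function(root_seed, cond_idx, rep_idx) {
  ((root_seed %% 1000003) * 1009 + cond_idx * 10007 + rep_idx * 101) %%
    2147483647L + 1
}

#' Run the full condition grid
#'
#' Runs `n_replicates` independent simulations for every combination of
#' substrate condition and genotype in the grid and summarises each
#' condition. Replicate seeds are derived deterministically from
#' `(root_seed, condition index, replicate index)`, so the whole table is
#' reproducible from the root seed alone.
#'
#' @param grid a grid specification from [make_default_grid] (or a
#'   compatible list with elements `substrates` (named list of
#'   [sls_params]), `genotypes` (character), `n_replicates`, `root_seed`,
#'   and optional `clutch`, `motors`, `sim` overrides).
#' @param n_replicates override of the grid's replicate count.
#' @param root_seed override of the grid's root seed.
#' @return An object of class `condition_grid`: list with `summary` (one
#'   row per condition) and `replicates` (per-replicate scaled FA length and
#'   flow), plus the configuration used.
#' @export
run_condition_grid <- function(grid = make_default_grid(),
                               n_replicates = NULL, root_seed = NULL) {
  if (is.null(grid$substrates) || length(grid$substrates) == 0)
    stop("grid must define at least one substrate condition block")
  if (is.null(grid$genotypes) || length(grid$genotypes) == 0)
    stop("grid must define a genotype list")
  n_rep <- if (!is.null(n_replicates)) n_replicates else grid$n_replicates
  seed0 <- if (!is.null(root_seed)) root_seed else grid$root_seed
  clutch <- if (!is.null(grid$clutch)) grid$clutch else clutch_params()
  motors <- if (!is.null(grid$motors)) grid$motors else motor_params()
  sim <- if (!is.null(grid$sim)) grid$sim else sim_config()
  if (n_rep < 2) stop("n_replicates must be >= 2")

  summaries <- list()
  reps <- list()
  cond_idx <- 0L
  for (gt_label in grid$genotypes) {
    gt <- genotype(gt_label,
                   koff_factor = grid$koff_factors[[gt_label]])
    for (sub_name in names(grid$substrates)) {
      cond_idx <- cond_idx + 1L
      cond <- paste(sub_name, gt_label, sep = "_")
      results <- lapply(seq_len(n_rep), function(i) {
        cfg <- sim
        cfg$seed <- replicate_seed(seed0, cond_idx, i)
        run_simulation(clutch, motors, grid$substrates[[sub_name]], gt, cfg)
      })
      s <- summarise_condition(results, condition = cond)
      s$substrate <- sub_name
      s$genotype <- gt_label
      summaries[[cond]] <- s
      reps[[cond]] <- cbind(attr(s, "replicates"),
                            substrate = sub_name, genotype = gt_label)
    }
  }
  summary <- do.call(rbind, c(summaries, make.row.names = FALSE))
  attr(summary, "replicates") <- NULL
  class(summary) <- "data.frame"
  structure(list(summary = summary,
                 replicates = do.call(rbind, c(reps, make.row.names = FALSE)),
                 grid = grid, n_replicates = n_rep, root_seed = seed0),
            class = "condition_grid")
}

#' @export
print.condition_grid <- function(x, ...) {
  cat(sprintf("Condition grid: %d conditions x %d replicates (root seed %d)\n",
              nrow(x$summary), x$n_replicates, x$root_seed))
  print(x$summary, digits = 3)
  invisible(x)
}

# One-sided permutation p-value for mean(x) > mean(y) (label shuffles).
perm_p_greater <- function(x, y, n_perm = 2000) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), nx)
    if (mean(pool[idx]) - mean(pool[-idx]) >= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# One-sided permutation p-value for an interaction (difference of
# differences): D = (mean(a2)-mean(a1)) - (mean(b2)-mean(b1)); genotype
# labels are shuffled within each substrate. Returns P(D_perm <= D_obs).
perm_p_interaction_le <- function(a1, a2, b1, b2, n_perm = 2000) {
  obs <- (mean(a2) - mean(a1)) - (mean(b2) - mean(b1))
  p1 <- c(a1, b1); p2 <- c(a2, b2)
  n1 <- length(a1); n2 <- length(a2)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    i1 <- sample.int(length(p1), n1)
    i2 <- sample.int(length(p2), n2)
    d <- (mean(p2[i2]) - mean(p1[i1])) -
         (mean(p2[-i2]) - mean(p1[-i1]))
    if (d <= obs) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

#' Check the qualitative trends of the condition grid
#'
#' Evaluates the qualitative predictions of the model on a full
#' condition-grid table, on condition means:
#' \describe{
#'   \item{a}{control soft V+ focal-adhesion length exceeds soft V-.}
#'   \item{b}{control stiff V- FA length exceeds soft V-.}
#'   \item{c}{control soft V+ FA length exceeds stiff V+.}
#'   \item{d}{Piezo1 knockdown does not raise FA length in any condition.}
#'   \item{e}{within each stiffness pair the retrograde-flow ordering is
#'     anti-parallel to the FA-length ordering.}
#'   \item{f}{the knockdown attenuates the soft-pair viscous FA gain
#'     relative to control.}
#' }
#' Assertions a, b, c and e compare raw means. Assertions d and f are
#' directional claims on stochastic replicate means, so they are guarded by
#' one-sided permutation tests at `alpha`: they fail only when the data
#' significantly contradicts the claimed direction. Piezo1 assertions are
#' omitted when the grid contains a single genotype.
#'
#' @param grid a [run_condition_grid] result, or its `summary` data.frame
#'   (then d and f fall back to Welch approximations from mean/SD/n).
#' @param alpha significance level for the guarded assertions.
#' @param n_perm permutation count for the guarded assertions.
#' @return A data.frame of class `trend_report` with columns `assertion`,
#'   `description`, `statistic`, `p_value`, `pass`.
#' @export
trend_check <- function(grid, alpha = 0.05, n_perm = 2000) {
  if (inherits(grid, "condition_grid")) {
    tab <- grid$summary
    reps <- grid$replicates
  } else {
    tab <- grid
    reps <- NULL
  }
  need <- c("substrate", "genotype", "fa_mean", "flow_mean")
  if (!all(need %in% names(tab)))
    stop("grid summary must have columns: ", paste(need, collapse = ", "))
  m <- function(sub, gt, what = "fa_mean") {
    v <- tab[[what]][tab$substrate == sub & tab$genotype == gt]
    if (length(v) != 1) stop("missing condition block: ", sub, " / ", gt)
    v
  }
  rvals <- function(sub, gt) {
    if (is.null(reps)) return(NULL)
    reps$fa_length[reps$substrate == sub & reps$genotype == gt]
  }
  has_kd <- all(c("scRNA", "siPiezo1") %in% tab$genotype)

  rows <- list()
  add <- function(id, desc, stat, p, pass)
    rows[[id]] <<- data.frame(assertion = id, description = desc,
                              statistic = stat, p_value = p, pass = pass,
                              stringsAsFactors = FALSE)

  d_a <- m("soft_Vplus", "scRNA") - m("soft_Vminus", "scRNA")
  add("a", "scRNA soft V+ FA length > soft V-", d_a, NA, d_a > 0)
  d_b <- m("stiff_Vminus", "scRNA") - m("soft_Vminus", "scRNA")
  add("b", "scRNA stiff V- FA length > soft V-", d_b, NA, d_b > 0)
  d_c <- m("soft_Vplus", "scRNA") - m("stiff_Vplus", "scRNA")
  add("c", "scRNA soft V+ FA length > stiff V+", d_c, NA, d_c > 0)

  if (has_kd) {
    subs <- unique(tab$substrate)
    worst_p <- 1; worst_d <- -Inf
    for (sub in subs) {
      dd <- m(sub, "siPiezo1") - m(sub, "scRNA")
      x <- rvals(sub, "siPiezo1"); y <- rvals(sub, "scRNA")
      p <- if (!is.null(x)) perm_p_greater(x, y, n_perm)
           else welch_p_greater(tab, sub)
      if (p < worst_p) { worst_p <- p; worst_d <- dd }
    }
    # joint claim over all conditions: Bonferroni-adjusted guard
    add("d", "siPiezo1 FA length <= scRNA in every condition",
        worst_d, worst_p, worst_p > alpha / length(subs))
  }

  anti <- TRUE
  for (pair in list(c("soft_Vminus", "soft_Vplus"),
                    c("stiff_Vminus", "stiff_Vplus"))) {
    dfa <- m(pair[2], "scRNA") - m(pair[1], "scRNA")
    dfl <- m(pair[2], "scRNA", "flow_mean") - m(pair[1], "scRNA", "flow_mean")
    anti <- anti && (dfa * dfl < 0)
  }
  add("e", "flow ordering anti-parallel to FA ordering within each pair",
      NA, NA, anti)

  if (has_kd) {
    gap_sc <- m("soft_Vplus", "scRNA") - m("soft_Vminus", "scRNA")
    gap_si <- m("soft_Vplus", "siPiezo1") - m("soft_Vminus", "siPiezo1")
    D <- gap_sc - gap_si
    if (!is.null(reps)) {
      p <- perm_p_interaction_le(
        rvals("soft_Vminus", "scRNA"), rvals("soft_Vplus", "scRNA"),
        rvals("soft_Vminus", "siPiezo1"), rvals("soft_Vplus", "siPiezo1"),
        n_perm)
    } else p <- NA
    pass <- D >= 0 || (!is.na(p) && p > alpha)
    add("f", "siPiezo1 soft V+/V- gap attenuated relative to scRNA", D, p,
        pass)
  }

  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("trend_report", class(out))
  out
}

# Welch one-sided approximation (siPiezo1 > scRNA) from summary statistics,
# used when per-replicate values are unavailable.
welch_p_greater <- function(tab, sub) {
  gi <- tab$substrate == sub & tab$genotype == "siPiezo1"
  gc <- tab$substrate == sub & tab$genotype == "scRNA"
  se <- sqrt(tab$fa_sd[gi]^2 / tab$n_replicates[gi] +
             tab$fa_sd[gc]^2 / tab$n_replicates[gc])
  if (se == 0) return(if (tab$fa_mean[gi] > tab$fa_mean[gc]) 0 else 1)
  stats::pnorm((tab$fa_mean[gi] - tab$fa_mean[gc]) / se, lower.tail = FALSE)
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Trend report:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%s] %-55s %s\n", x$assertion[i], x$description[i],
                if (x$pass[i]) "PASS" else "FAIL"))
  invisible(x)
}

#' YAP nuclear/cytoplasmic measurement
#'
#' Integrated intensities and areas used for the area-normalised nuclear to
#' cytoplasmic YAP ratio. Cytoplasmic signal and area are derived as
#' `cellYAP - nucYAP` and `cellA - nucA`.
#'
#' @param nucYAP nuclear integrated YAP intensity, `>= 0`.
#' @param nucA nuclear area, `> 0`.
#' @param cellYAP whole-cell integrated YAP intensity, `>= nucYAP`.
#' @param cellA whole-cell area, `> nucA`.
#' @return An object of class `yap_measurement`.
#' @export
yap_measurement <- function(nucYAP, nucA, cellYAP, cellA) {
  stopifnot(nucYAP >= 0, nucA > 0, cellA > nucA, cellYAP >= nucYAP)
  structure(list(nucYAP = nucYAP, nucA = nucA,
                 cellYAP = cellYAP, cellA = cellA),
            class = "yap_measurement")
}

#' Nuclear to cytoplasmic YAP ratio
#'
#' Area-normalised ratio `(nucYAP/nucA) / (cytoYAP/cytoA)` with
#' `cytoYAP = cellYAP - nucYAP` and `cytoA = cellA - nucA`. Equals 1 for a
#' cell with uniform YAP intensity density.
#'
#' @param m a [yap_measurement].
#' @return Dimensionless ratio.
#' @examples
#' yap_ratio(yap_measurement(10, 2, 20, 12))  # 5
#' @export
yap_ratio <- function(m) {
  stopifnot(inherits(m, "yap_measurement"))
  cytoYAP <- m$cellYAP - m$nucYAP
  cytoA <- m$cellA - m$nucA
  if (cytoYAP <= 0 || cytoA <= 0)
    stop("undefined ratio: zero cytoplasmic signal or area")
  (m$nucYAP / m$nucA) / (cytoYAP / cytoA)
}
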