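#' Random point cloud with a minimum separation
#'
#' Uniform points in a cubic box, re-drawn until all pairwise distances
#' reach `min_separation` (bounded retries). Used as a substrate for
#' contact-number tests.
#'
#' @param n Number of points (>= 2).
#' @param box Box edge length, Angstroms.
#' @param min_separation Smallest allowed pairwise distance, Angstroms.
#' @param seed Integer seed; same seed, same cloud.
#' @return A tibble with columns `x`, `y`, `z`.
#' @examples
#' synth_point_cloud(5, seed = 1)
#' @export
synth_point_cloud <- function(n, box = 30, min_separation = 1.5, seed = 1) {
  stopifnot(n >= 2, box > 0, min_separation >= 0)
  withr::with_seed(seed, {
    for (attempt in 1:200) {
      xyz <- matrix(stats::runif(3 * n, 0, box), ncol = 3)
      if (n < 2 || min(stats::dist(xyz)) >= min_separation) {
        return(tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
      }
    }
    rlang::abort("could not place points at the requested separation; enlarge the box")
  })
}

#' Synthetic pseudo-protein structure
#'
#' Builds a compact pseudo-structure for parser/ASA/WCN testing: residues
#' laid out along a boustrophedon path on a cubic lattice (3.8 Angstrom
#' spacing, the C-alpha virtual bond length), each with backbone N, CA, C,
#' O atoms and, except for glycine, 1-4 carbon side-chain pseudo-atoms
#' near the C-alpha. The result is writable as a valid PDB file and
#' round-trips through [read_structure()]. Interior lattice positions are
#' buried; corner/edge positions are solvent-exposed.
#'
#' @param n_residues Number of residues (>= 1).
#' @param seed Integer seed.
#' @param p_glycine Probability that a residue is glycine (no side chain).
#' @return A `deltol_structure` tibble.
#' @examples
#' synth_structure(5, seed = 1)
#' @export
synth_structure <- function(n_residues, seed = 1, p_glycine = 0.15) {
  stopifnot(n_residues >= 1)
  m <- ceiling(n_residues^(1 / 3))
  # boustrophedon walk over the lattice keeps consecutive residues adjacent
  grid <- expand.grid(i = 0:(m - 1), j = 0:(m - 1), k = 0:(m - 1))
  grid$i <- ifelse(grid$j %% 2 == 0, grid$i, m - 1 - grid$i)
  grid$j <- ifelse(grid$k %% 2 == 0, grid$j, m - 1 - grid$j)
  ca <- as.matrix(grid[seq_len(n_residues), ]) * 3.8
  withr::with_seed(seed, {
    resnames <- ifelse(stats::runif(n_residues) < p_glycine, "GLY",
                       sample(setdiff(.standard_aa, "GLY"), n_residues,
                              replace = TRUE))
    rows <- vector("list", n_residues)
    sc_names <- c("CB", "CG", "CD", "CE")
    for (i in seq_len(n_residues)) {
      p <- unname(ca[i, ])
      atoms <- tibble::tibble(
        atom = c("N", "CA", "C", "O"),
        element = c("N", "C", "C", "O"),
        x = p[1] + c(-1.2, 0, 1.2, 1.6),
        y = p[2] + c(-0.6, 0, 0.6, 1.6),
        z = p[3] + c(0.3, 0, -0.3, 0.3)
      )
      if (resnames[i] != "GLY") {
        n_sc <- sample(1:4, 1)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        sc <- tibble::tibble(
          atom = sc_names[seq_len(n_sc)],
          element = "C",
          x = p[1] + dir[1] * 1.5 * seq_len(n_sc) * 0.8,
          y = p[2] + dir[2] * 1.5 * seq_len(n_sc) * 0.8,
          z = p[3] + dir[3] * 1.5 * seq_len(n_sc) * 0.8
        )
        atoms <- dplyr::bind_rows(atoms, sc)
      }
      atoms$chain <- "A"
      atoms$resno <- i
      atoms$icode <- ""
      atoms$resname <- resnames[i]
      atoms$occupancy <- 1
      atoms$res_index <- i
      rows[[i]] <- atoms
    }
  })
  out <- purrr::list_rbind(rows)
  out <- dplyr::select(out, "chain", "resno", "icode", "resname", "atom",
                       "element", "x", "y", "z", "occupancy", "res_index")
  new_structure(out, id = sprintf("synth%d", n_residues))
}

#' Parameters for the synthetic feature-table generator
#'
#' The defaults emulate the structure of the eGFP deletion study: 72
#' mutants split 34 tolerated / 38 non-tolerated, with the tolerated class
#' more solvent-exposed (higher RSA), less packed (lower WCN), more
#' energetically favorable after design (more negative mean score), and
#' secondary-structure category probabilities taken from the published
#' per-category counts (loop-heavy for tolerated, sheet-heavy for
#' non-tolerated). Two label modes exist: `"class_conditional"` draws a
#' fixed class split and then features from per-class distributions;
#' `"generative_logistic"` draws features from the pooled distributions
#' and labels from a logistic model with the given coefficients.
#'
#' @param n_mutants Number of rows.
#' @param n_tolerated Number of tolerated rows (class-conditional mode).
#' @param mode `"class_conditional"` or `"generative_logistic"`.
#' @param rsa,wcn,score Per-class `c(mean, sd)` pairs in named lists with
#'   elements `tolerated` and `non_tolerated` (class-conditional mode).
#' @param ss_probs Per-class loop/helix/sheet probability vectors.
#' @param coefficients Named numeric vector for the generative-logistic
#'   mode: `intercept` plus any of `rsa`, `wcn`, `mean_score`, `ss_loop`,
#'   `ss_sheet` (helix is the reference level).
#' @param feature_dist Pooled feature distributions for the generative
#'   mode: list with `rsa`, `wcn`, `mean_score` as `c(mean, sd)` and
#'   `ss_probs` (length-3 probabilities).
#' @param seed Integer seed.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(
    n_mutants = 72,
    n_tolerated = 34,
    mode = c("class_conditional", "generative_logistic"),
    rsa = list(tolerated = c(0.40, 0.18), non_tolerated = c(0.20, 0.12)),
    wcn = list(tolerated = c(0.16, 0.05), non_tolerated = c(0.26, 0.06)),
    score = list(tolerated = c(-515, 10), non_tolerated = c(-495, 12)),
    ss_probs = list(tolerated = c(loop = 18, helix = 8, sheet = 8) / 34,
                    non_tolerated = c(loop = 5, helix = 4, sheet = 29) / 38),
    coefficients = c(intercept = 0),
    feature_dist = list(rsa = c(0.30, 0.18), wcn = c(0.21, 0.07),
                        mean_score = c(-505, 14),
                        ss_probs = c(loop = 0.32, helix = 0.17, sheet = 0.51)),
    seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_mutants >= 1, n_tolerated >= 0, n_tolerated <= n_mutants)
  for (p in list(ss_probs$tolerated, ss_probs$non_tolerated, feature_dist$ss_probs)) {
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      rlang::abort("secondary-structure probabilities must be nonnegative and sum to 1")
    }
  }
  for (d in c(rsa, wcn, score,
              feature_dist[c("rsa", "wcn", "mean_score")])) {
    if (d[2] <= 0) rlang::abort("distribution scales must be positive")
  }
  if (!"intercept" %in% names(coefficients)) {
    rlang::abort("coefficients must include an intercept")
  }
  structure(
    list(n_mutants = n_mutants, n_tolerated = n_tolerated, mode = mode,
         rsa = rsa, wcn = wcn, score = score, ss_probs = ss_probs,
         coefficients = coefficients, feature_dist = feature_dist,
         seed = seed),
    class = "synth_params"
  )
}

draw_ss <- function(n, probs) {
  factor(sample(c("loop", "helix", "sheet"), n, replace = TRUE, prob = probs),
         levels = .ss_levels)
}

#' Synthetic feature table with known ground truth
#'
#' Generates a per-mutant feature table under the configuration of
#' [synth_params()]. The ground truth (the parameter object and, in
#' generative-logistic mode, the per-row linear predictor and tolerance
#' probability) is attached as `attr(, "truth")`.
#'
#' @param params A `synth_params` object.
#' @return A feature-table tibble (`mutant_id`, `rsa`, `wcn`, `ss`,
#'   `mean_score`, `functional`) with a `truth` attribute.
#' @examples
#' tab <- synth_feature_table(synth_params(seed = 42))
#' table(tab$functional)
#' @export
synth_feature_table <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  n <- params$n_mutants
  withr::with_seed(params$seed, {
    if (params$mode == "class_conditional") {
      functional <- sample(rep(c(TRUE, FALSE),
                               c(params$n_tolerated, n - params$n_tolerated)))
      cls <- ifelse(functional, "tolerated", "non_tolerated")
      draw_cc <- function(d) {
        stats::rnorm(n,
                     mean = vapply(cls, function(c) d[[c]][1], numeric(1)),
                     sd = vapply(cls, function(c) d[[c]][2], numeric(1)))
      }
      rsa <- draw_cc(params$rsa)
      wcn <- draw_cc(params$wcn)
      mean_score <- draw_cc(params$score)
      ss <- factor(rep(NA_character_, n), levels = .ss_levels)
      for (c in c("tolerated", "non_tolerated")) {
        idx <- cls == c
        ss[idx] <- draw_ss(sum(idx), params$ss_probs[[c]])
      }
      truth <- list(params = params)
    } else {
      fd <- params$feature_dist
      rsa <- stats::rnorm(n, fd$rsa[1], fd$rsa[2])
      wcn <- stats::rnorm(n, fd$wcn[1], fd$wcn[2])
      mean_score <- stats::rnorm(n, fd$mean_score[1], fd$mean_score[2])
      ss <- draw_ss(n, fd$ss_probs)
      b <- params$coefficients
      eta <- rep(b[["intercept"]], n)
      terms <- list(rsa = rsa, wcn = wcn, mean_score = mean_score,
                    ss_loop = as.numeric(ss == "loop"),
                    ss_sheet = as.numeric(ss == "sheet"))
      for (nm in intersect(names(b), names(terms))) {
        eta <- eta + b[[nm]] * terms[[nm]]
      }
      prob <- stats::plogis(eta)
      functional <- stats::runif(n) < prob
      truth <- list(params = params, eta = eta, prob = prob)
    }
    out <- tibble::tibble(
      mutant_id = sprintf("m%03d", seq_len(n)),
      rsa = rsa, wcn = wcn, ss = ss, mean_score = mean_score,
      functional = functional
    )
    attr(out, "truth") <- truth
    out
  })
}

#' Binormal score sample with closed-form AUC
#'
#' Draws classifier scores from two normal distributions (negatives from
#' `N(mu_neg, sd_neg)`, positives from `N(mu_pos, sd_pos)`). The
#' theoretical AUC of such scores is
#' \eqn{\Phi((\mu_+ - \mu_-) / \sqrt{\sigma_-^2 + \sigma_+^2})},
#' returned alongside the sample as an exact oracle for empirical AUCs.
#'
#' @param n_neg,n_pos Class sizes.
#' @param mu_neg,mu_pos Class means.
#' @param sd_neg,sd_pos Class standard deviations (> 0).
#' @param seed Integer seed.
#' @return A list: `data` (tibble of `score`, `label`), `theoretical_auc`.
#' @examples
#' binormal_scores(50, 50, mu_pos = 1, seed = 1)$theoretical_auc
#' @export
binormal_scores <- function(n_neg, n_pos, mu_neg = 0, mu_pos = 1,
                            sd_neg = 1, sd_pos = 1, seed = 1) {
  if (sd_neg <= 0 || sd_pos <= 0) rlang::abort("standard deviations must be positive")
  stopifnot(n_neg >= 1, n_pos >= 1)
  withr::with_seed(seed, {
    data <- tibble::tibble(
      score = c(stats::rnorm(n_neg, mu_neg, sd_neg),
                stats::rnorm(n_pos, mu_pos, sd_pos)),
      label = rep(c(FALSE, TRUE), c(n_neg, n_pos))
    )
  })
  list(
    data = data,
    theoretical_auc = stats::pnorm((mu_pos - mu_neg) /
                                     sqrt(sd_neg^2 + sd_pos^2))
  )
}

#' Write synthetic per-mutant score files
#'
#' Emits one whitespace-delimited score table per mutant (column
#' `total_score`, nominally 100 rows) with class-conditional normal
#' totals: tolerated mutants draw from a lower (more favorable) mean.
#' Files are parseable by [parse_score_table()].
#'
#' @param mutant_ids Character vector of mutant ids (file stems).
#' @param labels Logical vector, `TRUE` = tolerated.
#' @param out_dir Output directory (created if needed).
#' @param n_models Rows per file.
#' @param tolerated,non_tolerated `c(mean, sd)` of the totals per class.
#' @param seed Integer seed.
#' @return A tibble recording per mutant the file path and the realized
#'   sample mean (`mean_score`) — the ground truth for round-trip checks.
#' @export
synth_score_files <- function(mutant_ids, labels, out_dir, n_models = 100,
                              tolerated = c(-515, 10),
                              non_tolerated = c(-495, 12), seed = 1) {
  stopifnot(length(mutant_ids) == length(labels), !anyNA(labels))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("cannot create output directory: ", out_dir))
  }
  withr::with_seed(seed, {
    rows <- purrr::map2(mutant_ids, labels, function(id, lab) {
      d <- if (lab) tolerated else non_tolerated
      scores <- stats::rnorm(n_models, d[1], d[2])
      path <- file.path(out_dir, paste0(id, ".sc"))
      writeLines(
        c("total_score description",
          sprintf("%.4f %s_%04d", scores, id, seq_along(scores))),
        path
      )
      tibble::tibble(mutant_id = id, path = path,
                     mean_score = mean(scores), n_models = n_models)
    })
    purrr::list_rbind(rows)
  })
}
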