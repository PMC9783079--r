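## datasets: build/split/persist/reload pools; import experimental CSVs.

.fmt <- function(x) sprintf("%.17g", x)   # full-precision text round trip

#' Build, split and describe a dataset
#'
#' Builds a class-balanced pool via the sampler, then splits it stratified by
#' mechanism at the system level (a system's scan rates never leak across
#' splits), and records a manifest sufficient to regenerate the dataset from
#' its seed alone. Currents are stored noiseless; noise is always re-injected
#' downstream, so one dataset serves every sigma experiment.
#'
#' @param per_mech_count Systems per mechanism.
#' @param domain A [parameter_domain()].
#' @param solver A [solver_config()].
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @param n Optionally force the number of scan rates per system.
#' @return A `cv_dataset`: list with `pool`, `splits` (`train`, `validation`,
#'   `test` index vectors) and `manifest`.
#' @export
make_dataset <- function(per_mech_count, domain = parameter_domain(),
                         solver = solver_config(), fractions = c(0.8, 0.1, 0.1),
                         seed = 1L, n = NULL) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            all(fractions >= 0))
  pool <- build_labeled_pool(per_mech_count, domain, solver, seed = seed, n = n)
  splits <- split_pool(pool, fractions, seed = seed + 1L)
  counts <- lapply(splits, function(ix) tabulate(pool$label[ix], 5L))
  manifest <- list(
    per_mech_count = per_mech_count,
    fractions = fractions, seed = seed, split_seed = seed + 1L,
    counts = lapply(counts, function(ct) stats::setNames(as.list(ct),
                                                         mechanism_levels())),
    sigma_convention = "noise injected downstream, never persisted",
    cycle = pool$meta$cycle,
    solver = unclass(solver),
    domain = lapply(unclass(domain), function(z) z),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  structure(list(pool = pool, splits = splits, manifest = manifest),
            class = "cv_dataset")
}

#' Stratified system-level split of a pool
#'
#' @param pool A `cv_pool`.
#' @param fractions Train/validation/test fractions.
#' @param seed Seed for the within-class shuffles.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
split_pool <- function(pool, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(pool, "cv_pool"), length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-9)
  set.seed(seed)
  train <- validation <- test <- integer(0)
  for (mech in 1:5) {
    ix <- sample(which(pool$label == mech))
    nall <- length(ix)
    nva <- round(fractions[2] * nall)
    nte <- round(fractions[3] * nall)
    ntr <- nall - nva - nte
    train <- c(train, ix[seq_len(ntr)])
    validation <- c(validation, ix[ntr + seq_len(nva)])
    test <- c(test, ix[ntr + nva + seq_len(nte)])
  }
  list(train = sort(train), validation = sort(validation), test = sort(test))
}

#' Persist a dataset to a plain-text directory container
#'
#' Writes `manifest.yaml`, `labels.csv` (system, mechanism, split),
#' `systems.csv` (full parameter snapshot per system), `potentials.csv` and
#' `currents.csv` (analysis-cycle half-sweep samples at full numeric
#' precision). [load_dataset()] restores the dataset bit-identically.
#'
#' @param dataset A `cv_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cv_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pool <- dataset$pool
  yaml::write_yaml(dataset$manifest, file.path(dir, "manifest.yaml"))

  split_of <- rep("train", length(pool$label))
  split_of[dataset$splits$validation] <- "validation"
  split_of[dataset$splits$test] <- "test"
  utils::write.csv(data.frame(system = seq_along(pool$label),
                              mechanism = mechanism_levels()[pool$label],
                              split = split_of),
                   file.path(dir, "labels.csv"), row.names = FALSE)

  sysdf <- do.call(rbind, lapply(seq_along(pool$systems), function(k) {
    s <- pool$systems[[k]]; p <- s$params; pr <- s$protocol
    data.frame(system = k, mechanism = s$mechanism,
               E0_1 = .fmt(p$E0_1), E0_2 = .fmt(p$E0_2 %||% NA_real_),
               k0 = .fmt(p$k0), alpha = .fmt(p$alpha), kf = .fmt(p$kf),
               kb = .fmt(p$kb), ki = .fmt(p$ki), kd = .fmt(p$kd),
               D = .fmt(p$D), C_bulk = .fmt(p$C_bulk), Cdl = .fmt(p$Cdl),
               E_start = .fmt(pr$E_start), E_vertex = .fmt(pr$E_vertex),
               n_cycles = pr$n_cycles, T = .fmt(pr$T),
               electrode_area = .fmt(pr$electrode_area),
               v_list = paste(.fmt(pr$v_list), collapse = ";"))
  }))
  utils::write.csv(sysdf, file.path(dir, "systems.csv"), row.names = FALSE)

  pots <- do.call(rbind, lapply(seq_along(pool$raw), function(k) {
    r <- pool$raw[[k]]
    rbind(data.frame(system = k, half = "forward",
                     sample = seq_along(r$Ef), E = .fmt(r$Ef)),
          data.frame(system = k, half = "reverse",
                     sample = seq_along(r$Er), E = .fmt(r$Er)))
  }))
  utils::write.csv(pots, file.path(dir, "potentials.csv"), row.names = FALSE)

  curs <- do.call(rbind, lapply(seq_along(pool$raw), function(k) {
    r <- pool$raw[[k]]
    do.call(rbind, lapply(seq_along(r$v), function(j) {
      rbind(data.frame(system = k, scan = j, v = .fmt(r$v[j]), half = "forward",
                       sample = seq_len(nrow(r$If)), i = .fmt(r$If[, j])),
            data.frame(system = k, scan = j, v = .fmt(r$v[j]), half = "reverse",
                       sample = seq_len(nrow(r$Ir)), i = .fmt(r$Ir[, j])))
    }))
  }))
  utils::write.csv(curs, file.path(dir, "currents.csv"), row.names = FALSE)
  invisible(dir)
}

#' Reload a persisted dataset
#'
#' @param dir Directory written by [save_dataset()].
#' @return A `cv_dataset`.
#' @export
load_dataset <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  sysdf <- utils::read.csv(file.path(dir, "systems.csv"),
                           stringsAsFactors = FALSE)
  pots <- utils::read.csv(file.path(dir, "potentials.csv"),
                          stringsAsFactors = FALSE)
  curs <- utils::read.csv(file.path(dir, "currents.csv"),
                          stringsAsFactors = FALSE)
  # integral-looking values ("0", "1") parse as integer; restore doubles
  for (col in c("E0_1", "E0_2", "k0", "alpha", "kf", "kb", "ki", "kd", "D",
                "C_bulk", "Cdl", "E_start", "E_vertex", "T", "electrode_area"))
    sysdf[[col]] <- as.numeric(sysdf[[col]])
  pots$E <- as.numeric(pots$E)
  curs$i <- as.numeric(curs$i)
  curs$v <- as.numeric(curs$v)

  systems <- lapply(seq_len(nrow(sysdf)), function(k) {
    s <- sysdf[k, ]
    system_spec(s$mechanism, E0_1 = s$E0_1,
                E0_2 = if (is.na(s$E0_2)) NULL else s$E0_2,
                k0 = s$k0, alpha = s$alpha, kf = s$kf, kb = s$kb, ki = s$ki,
                kd = s$kd, D = s$D, C_bulk = s$C_bulk, Cdl = s$Cdl,
                v_list = as.numeric(strsplit(s$v_list, ";")[[1]]),
                E_start = s$E_start, E_vertex = s$E_vertex,
                n_cycles = s$n_cycles, T = s$T,
                electrode_area = s$electrode_area)
  })
  raw <- lapply(seq_len(nrow(sysdf)), function(k) {
    pk <- pots[pots$system == k, ]
    ck <- curs[curs$system == k, ]
    Ef <- pk$E[pk$half == "forward"][order(pk$sample[pk$half == "forward"])]
    Er <- pk$E[pk$half == "reverse"][order(pk$sample[pk$half == "reverse"])]
    scans <- sort(unique(ck$scan))
    v <- vapply(scans, function(j) ck$v[ck$scan == j][1], 0)
    If <- vapply(scans, function(j) {
      z <- ck[ck$scan == j & ck$half == "forward", ]
      z$i[order(z$sample)]
    }, numeric(length(Ef)))
    Ir <- vapply(scans, function(j) {
      z <- ck[ck$scan == j & ck$half == "reverse", ]
      z$i[order(z$sample)]
    }, numeric(length(Er)))
    list(v = v, Ef = Ef, Er = Er, If = matrix(If, ncol = length(scans)),
         Ir = matrix(Ir, ncol = length(scans)))
  })
  pool <- structure(list(systems = systems, raw = raw,
                         label = .mech_id(labels$mechanism),
                         meta = list(seed = manifest$seed,
                                     cycle = manifest$cycle,
                                     solver = manifest$solver)),
                    class = "cv_pool")
  splits <- list(train = labels$system[labels$split == "train"],
                 validation = labels$system[labels$split == "validation"],
                 test = labels$system[labels$split == "test"])
  structure(list(pool = pool, splits = splits, manifest = manifest),
            class = "cv_dataset")
}

#' Import experimental cyclic voltammograms from CSV
#'
#' Reads the package's voltammogram exchange schema: header columns `cycle`,
#' `scan_rate_V_per_s`, `E_V`, `i_A_per_cm2`, `direction`
#' (`"forward"`/`"reverse"`). Rows may arrive in any order; they are sorted
#' canonically (ascending scan rate and cycle; forward half-sweeps by
#' descending potential, reverse by ascending, matching the reductive-forward
#' convention — downstream interpolation is order-independent).
#'
#' @param path CSV file path.
#' @param label Optional known mechanism label.
#' @return A `cv_voltset` ready for [preprocess_voltset()] and prediction.
#' @export
import_experimental_csv <- function(path, label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cycle", "scan_rate_V_per_s", "E_V", "i_A_per_cm2", "direction")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("schema violation in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  for (col in c("cycle", "scan_rate_V_per_s", "E_V", "i_A_per_cm2")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0)
      stop("schema violation in ", path, ": non-numeric ", col,
           " at data line(s) ", paste(utils::head(bad + 1L, 5), collapse = ", "))
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!all(df$direction %in% c("forward", "reverse")))
    stop("schema violation in ", path,
         ": direction must be 'forward' or 'reverse'")
  if (any(df$scan_rate_V_per_s <= 0))
    stop("schema violation in ", path, ": scan rates must be positive (V/s)")
  vs <- sort(unique(df$scan_rate_V_per_s))
  if (length(vs) > 6)
    stop("more than 6 scan rates in ", path, "; the input tensor holds up to 6")
  curves <- lapply(vs, function(v) {
    d <- df[df$scan_rate_V_per_s == v, ]
    parts <- lapply(sort(unique(d$cycle)), function(cy) {
      dc <- d[d$cycle == cy, ]
      fw <- dc[dc$direction == "forward", ]
      rv <- dc[dc$direction == "reverse", ]
      fw <- fw[order(-fw$E_V), ]
      rv <- rv[order(rv$E_V), ]
      rbind(fw, rv)
    })
    d <- do.call(rbind, parts)
    out <- data.frame(cycle = d$cycle, E = d$E_V, i = d$i_A_per_cm2,
                      i_far = NA_real_, direction = d$direction,
                      stringsAsFactors = FALSE)
    attr(out, "v") <- v
    attr(out, "min_conc_rel") <- NA_real_
    class(out) <- c("cv_voltammogram", "data.frame")
    out
  })
  structure(list(curves = curves, v = vs, system = NULL, label = label),
            class = "cv_voltset")
}
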