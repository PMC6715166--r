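# Batch orchestration: manifest-driven trait extraction, gridding and the
# disparity / range-shift reports, with reproducible configuration.

#' Run configuration for batch processing
#'
#' Defaults equal the standard protocol: 100,000 surface points per cloud,
#' a 75-point commissure resample, 100 thickness bins, a 100 x 101
#' semilandmark grid, 1000 reshuffles and 23 retained axes.
#'
#' @param n_points surface points per Poisson-disk cloud.
#' @param n_commissure commissure resample count.
#' @param n_bins thickness histogram bins.
#' @param n_sections,n_sub semilandmark grid dimensions.
#' @param n_perm permutation count for null models.
#' @param n_axes axis retention policy: fixed count, `"variance"` or
#'   `"rmse"` (see [pca_morphospace()]).
#' @param seed integer RNG seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(n_points = 100000L, n_commissure = 75L, n_bins = 100L,
                       n_sections = 100L, n_sub = 101L, n_perm = 1000L,
                       n_axes = 23L, seed = 0L) {
  cfg <- list(n_points = as.integer(n_points),
              n_commissure = as.integer(n_commissure),
              n_bins = as.integer(n_bins),
              n_sections = as.integer(n_sections), n_sub = as.integer(n_sub),
              n_perm = as.integer(n_perm), n_axes = n_axes,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_points", "n_commissure", "n_bins", "n_sections",
                         "n_sub", "n_perm")])
  if (any(counts <= 0L)) stop("all configuration counts must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::yaml.load_file(path))
}

# polynomial rolling hash of the serialized configuration; carried by outputs
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

process_valve <- function(mesh_path, commissure_path, side, cfg) {
  mesh <- clean_largest_component(load_valve_mesh(mesh_path))
  curve <- read_commissure_csv(commissure_path)
  split <- split_at_commissure(mesh, curve)
  q <- quarter_landmarks(curve, n_resample = cfg$n_commissure, side = side,
                         reference_point = colMeans(mesh$vertices))
  cloud_whole <- poisson_disk_points(mesh, cfg$n_points, seed = cfg$seed)
  cloud_ext <- poisson_disk_points(split$exterior, cfg$n_points, seed = cfg$seed + 1L)
  cloud_int <- poisson_disk_points(split$interior, cfg$n_points, seed = cfg$seed + 2L)
  cloud_ext$source <- "exterior"; cloud_int$source <- "interior"
  list(mesh = mesh, split = split, quarters = q, cloud = cloud_whole,
       cloud_ext = cloud_ext, cloud_int = cloud_int, side = side)
}

#' Extract the trait table for a manifest of valves
#'
#' The manifest CSV lists one row per valve: `specimen_id, species, region,
#' family, functional_group, side, equivalve, mesh, commissure` (paths
#' relative to the manifest). Equivalve specimens contribute one valve,
#' inequivalve specimens two rows sharing a `specimen_id`. Per-specimen
#' failures are logged and skipped; the run continues.
#'
#' @param manifest path to the manifest CSV, or a data.frame.
#' @param out_csv optional path for the output trait CSV.
#' @param config a [run_config()].
#' @return data.frame: `specimen_id, species, region, family,
#'   functional_group, centroid_size, TSV, TIV, propSV, max_ornament, q99,
#'   q98, q95`, with the failed specimen ids in attribute `"failures"` and
#'   the configuration hash in attribute `"config_hash"`.
#' @export
run_traits <- function(manifest, out_csv = NULL, config = run_config()) {
  man <- if (is.data.frame(manifest)) manifest else read.csv(manifest, stringsAsFactors = FALSE)
  if (nrow(man) == 0L) stop("empty manifest")
  base_dir <- if (is.data.frame(manifest)) "." else dirname(manifest)
  need <- c("specimen_id", "species", "region", "family", "functional_group",
            "side", "equivalve", "mesh", "commissure")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  man$side <- ifelse(toupper(substr(man$side, 1, 1)) == "R", "right", "left")
  man$equivalve <- tolower(as.character(man$equivalve)) %in% c("true", "t", "1", "yes")
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  ids <- unique(man$specimen_id)
  rows <- list(); failures <- character(0)
  for (id in ids) {
    sub <- man[man$specimen_id == id, , drop = FALSE]
    res <- tryCatch({
      valves <- lapply(seq_len(nrow(sub)), function(i)
        process_valve(resolve(sub$mesh[i]), resolve(sub$commissure[i]),
                      sub$side[i], config))
      vs <- volume_summary(lapply(valves, function(v)
        list(whole = v$mesh, interior = v$split$interior, cloud = v$cloud)),
        equivalve = sub$equivalve[1])
      # ornamentation from the first valve's thickness field
      tf <- thickness_field(valves[[1]]$cloud_ext, valves[[1]]$cloud_int,
                            n_bins = config$n_bins)
      os <- ornament_summary(tf)
      data.frame(specimen_id = id, species = sub$species[1],
                 region = sub$region[1], family = sub$family[1],
                 functional_group = sub$functional_group[1],
                 centroid_size = vs$body_centroid_size,
                 TSV = vs$TSV, TIV = vs$TIV, propSV = vs$propSV,
                 max_ornament = os$q100, q99 = os$q99, q98 = os$q98,
                 q95 = os$q95)
    }, error = function(e) {
      message(sprintf("specimen %s failed: %s", id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- c(failures, id) else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("all specimens failed")
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  attr(out, "config_hash") <- config_hash(config)
  if (!is.null(out_csv)) {
    con <- file(out_csv, "w")
    writeLines(sprintf("# config_hash: %s", config_hash(config)), con)
    write.csv(out, con, row.names = FALSE)
    close(con)
  }
  out
}

#' Build aligned semilandmark grids for a manifest of valves
#'
#' Runs the frame alignment and gridding for every specimen in the manifest
#' (using the first valve of inequivalve pairs, mirrored when it is a right
#' valve).
#'
#' @inheritParams run_traits
#' @return list with `grids`, `fixed` (quarter landmarks) and `ids`.
#' @export
run_grids <- function(manifest, config = run_config()) {
  man <- if (is.data.frame(manifest)) manifest else read.csv(manifest, stringsAsFactors = FALSE)
  base_dir <- if (is.data.frame(manifest)) "." else dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base_dir, p))
  man$side <- ifelse(toupper(substr(man$side, 1, 1)) == "R", "right", "left")
  ids <- unique(man$specimen_id)
  grids <- list(); fixed <- list()
  for (id in ids) {
    sub <- man[man$specimen_id == id, , drop = FALSE][1, , drop = FALSE]
    v <- process_valve(resolve(sub$mesh), resolve(sub$commissure), sub$side, config)
    av <- orient_and_scale_valve(v$split$interior, v$quarters, side = v$side)
    grids[[id]] <- build_semilandmark_grid(av, n_sections = config$n_sections,
                                           n_sub = config$n_sub, specimen_id = id)
    fixed[[id]] <- av$quarters
  }
  list(grids = grids, fixed = fixed, ids = ids)
}

#' Disparity report: GPA, PCA, group statistics, nulls and tests
#'
#' Accepts either aligned grids (a `procrustes_set`) or a precomputed score
#' matrix, plus per-specimen metadata, and produces the full between-group
#' report: observed disparity metrics, reshuffling nulls with 95% intervals,
#' Wilcoxon/Bonferroni and KS tests, for regions and for each family and
#' functional group shared between regions.
#'
#' @param scores specimen x axes matrix (e.g. `morphospace$scores`), or a
#'   `morphospace`.
#' @param meta data.frame with `region`, and optionally `family` and
#'   `functional_group`, one row per specimen in order.
#' @param config a [run_config()].
#' @param out_dir optional directory: writes `disparity.json` and
#'   `disparity.csv`.
#' @return list of class `disparity_report`: `fauna` (a
#'   [disparity_summary()]), `by_family`, `by_functional_group` (per-group
#'   observed metrics within each region), `exclusions`, `config_hash`.
#' @export
run_disparity <- function(scores, meta, config = run_config(), out_dir = NULL) {
  if (inherits(scores, "morphospace"))
    scores <- scores$scores[, seq_len(scores$n_axes), drop = FALSE]
  S <- as.matrix(scores)
  if (!"region" %in% names(meta)) stop("metadata must contain a 'region' column")
  if (nrow(meta) != nrow(S)) stop("metadata rows must match score rows")
  k <- if (is.numeric(config$n_axes)) min(config$n_axes, ncol(S)) else ncol(S)
  S <- S[, seq_len(k), drop = FALSE]
  fauna <- disparity_summary(S, meta$region, n_perm = config$n_perm,
                             seed = config$seed)
  subgroup_report <- function(col) {
    if (!col %in% names(meta)) return(NULL)
    regs <- sort(unique(meta$region))
    out <- list(); excl <- character(0)
    for (g in sort(unique(meta[[col]]))) {
      sel <- meta[[col]] == g
      sizes <- table(factor(meta$region[sel], levels = regs))
      if (any(sizes < 3L)) { excl <- c(excl, g); next }
      out[[g]] <- disparity_summary(S[sel, , drop = FALSE], meta$region[sel],
                                    n_perm = config$n_perm, seed = config$seed)
    }
    list(groups = out, excluded = excl)
  }
  fam <- subgroup_report("family")
  fg <- subgroup_report("functional_group")
  rep_obj <- structure(list(fauna = fauna, by_family = fam,
                            by_functional_group = fg,
                            exclusions = c(fam$excluded, fg$excluded),
                            n_axes = k,
                            config_hash = config_hash(config)),
                       class = "disparity_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    summarize <- function(ds) list(
      observed = ds$observed,
      nulls = lapply(ds$nulls, function(tb) tb[, c("group", "observed",
                                                   "null_mean", "ci_lo", "ci_hi")]),
      tests = ds$tests)
    json <- list(config_hash = rep_obj$config_hash, n_axes = k,
                 fauna = summarize(fauna),
                 families = lapply(fam$groups, summarize),
                 functional_groups = lapply(fg$groups, summarize),
                 exclusions = rep_obj$exclusions)
    jsonlite::write_json(json, file.path(out_dir, "disparity.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write.csv(fauna$observed, file.path(out_dir, "disparity.csv"),
              row.names = FALSE)
  }
  rep_obj
}

#' @export
print.disparity_report <- function(x, ...) {
  cat(sprintf("disparity_report (config %s, %d axes)\n", x$config_hash, x$n_axes))
  print(x$fauna)
  if (length(x$exclusions))
    cat("subgroups excluded by the size rule:", paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Range-shift report across traits
#'
#' Scales each trait (without centering), computes per-subgroup changes in
#' minima and maxima between the two regions, and classifies every subgroup
#' into the nine fields, separately per trait and per subgroup kind (family
#' / functional group).
#'
#' @param traits data.frame with `region`, `family`, `functional_group` and
#'   the trait columns.
#' @param trait_cols trait column names, default
#'   `c("centroid_size", "max_ornament", "propSV")`.
#' @param focal focal region (defaults to the alphabetically first).
#' @param out_dir optional directory: writes `range_shift.csv` and
#'   `range_shift_thresholds.json`.
#' @param config a [run_config()].
#' @return data.frame with one classified row per trait x kind x subgroup.
#' @export
run_range_shift <- function(traits, trait_cols = c("centroid_size",
                                                   "max_ornament", "propSV"),
                            focal = NULL, out_dir = NULL,
                            config = run_config()) {
  stopifnot(all(trait_cols %in% names(traits)))
  scaled <- scale_not_center(traits[, trait_cols, drop = FALSE])
  out <- list(); thresholds <- list()
  for (tc in trait_cols) {
    for (kind in c("family", "functional_group")) {
      if (!kind %in% names(traits)) next
      rd <- suppressMessages(
        range_deltas(scaled[, tc], traits$region, traits[[kind]],
                     focal = focal, kind = kind))
      if (is.null(rd) || nrow(rd) < 3L) next
      cf <- classify_fields(rd)
      cf$trait <- tc
      out[[paste(tc, kind)]] <- as.data.frame(cf)
      thr <- attr(cf, "thresholds"); thr$trait <- tc; thr$kind <- kind
      thresholds[[paste(tc, kind)]] <- thr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "thresholds") <- do.call(rbind, thresholds)
  attr(res, "config_hash") <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res, file.path(out_dir, "range_shift.csv"), row.names = FALSE)
    jsonlite::write_json(list(config_hash = config_hash(config),
                              thresholds = attr(res, "thresholds")),
                         file.path(out_dir, "range_shift_thresholds.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  res
}
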