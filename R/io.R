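# Text-based on-disk formats: ESRI ASCII grids for raster layers, GeoJSON
# for region polygons, CSV for occurrences, JSON for ground truth + manifest.

#' Write a raster layer as an ESRI ASCII grid (.asc)
#'
#' @param r an [eco_raster()]
#' @param path output file
#' @param nodata NODATA sentinel written for `NA` cells
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  stopifnot(inherits(r, "eco_raster"))
  g <- r$geom
  hdr <- c(sprintf("ncols %d", g$nx), sprintf("nrows %d", g$ny),
           sprintf("xllcorner %.10g", g$origin[1]),
           sprintf("yllcorner %.10g", g$origin[2]),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %g", nodata))
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # .asc rows run top to bottom
  for (j in rev(seq_len(g$ny)))
    writeLines(paste(formatC(v[j, ], format = "g", digits = 8),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#'
#' @param path file path
#' @return an [eco_raster()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                 tolower(vapply(hdr, `[[`, "", 1)))
  g <- grid_geom(kv[["ncols"]], kv[["nrows"]], kv[["cellsize"]],
                 c(kv[["xllcorner"]], kv[["yllcorner"]]))
  rows <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  v <- do.call(rbind, rows)
  stopifnot(nrow(v) == g$ny, ncol(v) == g$nx)
  v <- v[rev(seq_len(g$ny)), , drop = FALSE]
  v[v == kv[["nodata_value"]]] <- NA
  eco_raster(v, g)
}

regions_to_geojson <- function(regions) {
  feat <- function(name) {
    poly <- regions[[name]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = name),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  }
  list(type = "FeatureCollection",
       features = lapply(c("domain", "pacific", "caribbean"), feat))
}

#' Write the synthetic bundle to disk
#'
#' Writes one `.asc` grid per layer, `occurrences.csv`, `regions.geojson`,
#' the ground-truth niches as `true_niches.json`, and `manifest.json` listing
#' every file with its md5 checksum plus the generating config.
#'
#' @param stack,niches,occurrences,regions components from
#'   [simulate_study_system()]
#' @param out_dir output directory (created if needed)
#' @param config the generating [sim_config()]
#' @return invisibly, the manifest list
#' @export
write_fixture_bundle <- function(stack, niches, occurrences, regions,
                                 out_dir, config) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir)
  files <- character()
  for (nm in stack$layer_names) {
    f <- file.path(out_dir, paste0("layer_", nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], f)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "occurrences.csv")
  write.csv(occurrences, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- file.path(out_dir, "regions.geojson")
  jsonlite::write_json(regions_to_geojson(regions), f, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, f)

  f <- file.path(out_dir, "true_niches.json")
  jsonlite::write_json(lapply(niches, function(n) list(
    species = n$species_id, season = n$season,
    center = as.numeric(n$center),
    covariance = unname(n$covariance),
    resident = n$resident, slope = n$slope)), f, auto_unbox = TRUE,
    digits = NA)
  files <- c(files, f)

  manifest <- list(
    seed = config$seed,
    config = unclass(config),
    files = lapply(files, function(fp) list(
      name = basename(fp), md5 = unname(tools::md5sum(fp)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a directory of `.asc` layers back into an environment stack
#'
#' @param dir directory containing `layer_*.asc` files
#' @return an `env_stack`
#' @export
read_env_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "^layer_.*\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no layer_*.asc files in ", dir)
  layers <- lapply(files, read_ascii_grid)
  names(layers) <- sub("^layer_(.*)\\.asc$", "\\1", basename(files))
  g <- layers[[1]]$geom
  for (l in layers) stopifnot(same_geom(l$geom, g))
  structure(list(layers = layers, geom = g, layer_names = names(layers)),
            class = "env_stack")
}
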