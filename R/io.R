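#' Write a trajectory as extended XYZ
#'
#' One block per frame: the particle count, then a comment line carrying
#' `Step=`, `Box="D L mode"` and `Properties=species:S:1:pos:R:3:image:I:1`,
#' then one line per particle: species label, x, y, z, image counter.  The
#' species-first column layout follows the common extended-XYZ dialect, so
#' standard viewers can read the file.
#'
#' @param trajectory a trajectory from [integrate_dynamics()].
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  g <- trajectory$spec$geometry
  labels <- c("M", "C", "W")[trajectory$species_recorded]
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(trajectory$frames)) {
    f <- trajectory$frames[[k]]
    img <- trajectory$frame_images[[k]]
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf(
      'Step=%d Box="%.8g %.8g %s" Properties=species:S:1:pos:R:3:image:I:1',
      trajectory$steps[k], g$diameter, g$length, g$mode), con)
    writeLines(sprintf("%s %.10g %.10g %.10g %d",
                       labels, f[, 1], f[, 2], f[, 3], img), con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory
#'
#' Inverse of [write_trajectory()].  Malformed input raises a parse error
#' naming the offending line.
#'
#' @param path file written by [write_trajectory()] (or any XYZ file in the
#'   species-first dialect).
#' @return A list of class `trajectory` with `frames`, `frame_images`,
#'   `steps`, `species_recorded` and `box` metadata (no spec attached).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("parse error at line 1: empty trajectory file")
  frames <- list(); images <- list(); steps <- integer(0)
  species <- NULL; box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*[0-9]+\\s*$", lines[i]))
      stop(sprintf("parse error at line %d: expected particle count", i))
    n <- as.integer(lines[i])
    if (n < 1) stop(sprintf("parse error at line %d: empty frame", i))
    if (i + 1L > length(lines))
      stop(sprintf("parse error at line %d: missing comment line", i + 1L))
    comment <- lines[i + 1L]
    step <- as.integer(sub(".*Step=([0-9]+).*", "\\1", comment))
    if (is.na(step)) step <- length(frames)
    bm <- regmatches(comment, regexec('Box="([^"]*)"', comment))[[1]]
    if (length(bm) == 2 && is.null(box)) {
      parts <- strsplit(trimws(bm[2]), "\\s+")[[1]]
      box <- list(diameter = as.numeric(parts[1]),
                  length = as.numeric(parts[2]),
                  mode = if (length(parts) > 2) parts[3] else "periodic")
    }
    if (i + 1L + n > length(lines))
      stop(sprintf("parse error at line %d: truncated frame (expected %d atoms)",
                   length(lines), n))
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    nf <- lengths(toks)
    if (any(nf < 4))
      stop(sprintf("parse error at line %d: expected species x y z [image]",
                   i + 1L + which(nf < 4)[1]))
    lab <- vapply(toks, `[`, character(1), 1)
    sp <- match(lab, c("M", "C", "W"))
    if (anyNA(sp))
      stop(sprintf("parse error at line %d: unknown species label",
                   i + 1L + which(is.na(sp))[1]))
    pos <- matrix(as.numeric(vapply(toks, function(t) t[2:4], character(3))),
                  ncol = 3, byrow = TRUE)
    if (anyNA(pos))
      stop(sprintf("parse error near line %d: non-numeric coordinate", i + 2L))
    img <- vapply(toks, function(t) if (length(t) >= 5) as.integer(t[5]) else 0L,
                  integer(1))
    if (is.null(species)) species <- sp
    frames[[length(frames) + 1L]] <- pos
    images[[length(images) + 1L]] <- img
    steps <- c(steps, step)
    i <- i + 2L + n
  }
  structure(list(frames = frames, frame_images = images, steps = steps,
                 species_recorded = species, box = box,
                 sample_stride = if (length(steps) > 1) diff(steps)[1] else 1L,
                 record = "file"),
            class = "trajectory")
}

#' Serialize a system specification to YAML
#'
#' @param spec a [system_spec()] (or a sweep specification list).
#' @param path output file.
#' @export
write_config <- function(spec, path) {
  yaml::write_yaml(spec_to_list(spec), path)
  invisible(path)
}

spec_to_list <- function(spec) {
  if (inherits(spec, "system_spec")) {
    list(
      kind = "system_spec",
      n_monomers = spec$n_monomers,
      monomer_diameter = spec$monomer_diameter,
      crowder_diameter = spec$crowder_diameter,
      phi_c = spec$phi_c,
      volume_convention = "nominal cylinder volume pi (D/2)^2 L",
      interactions = list(sigma = as.vector(spec$interactions$sigma),
                          epsilon = as.vector(spec$interactions$epsilon)),
      bonds = unclass(spec$bonds),
      dynamics = list(dt = spec$dynamics$dt, gamma = spec$dynamics$gamma,
                      temperature = spec$dynamics$temperature,
                      mass = as.list(spec$dynamics$mass)),
      geometry = unclass(spec$geometry),
      seed = spec$seed)
  } else unclass(spec)
}

#' Read a system specification from YAML
#'
#' @param path file written by [write_config()].
#' @return A [system_spec()].
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!identical(x$kind, "system_spec"))
    stop("config file does not describe a system_spec")
  sig <- matrix(unlist(x$interactions$sigma), 3, 3)
  eps <- matrix(unlist(x$interactions$epsilon), 3, 3)
  sp <- c("monomer", "crowder", "wall")
  dimnames(sig) <- dimnames(eps) <- list(sp, sp)
  tab <- structure(list(sigma = sig, epsilon = eps), class = "interaction_table")
  validate_interaction_table(tab)
  system_spec(
    n_monomers = x$n_monomers,
    monomer_diameter = x$monomer_diameter,
    crowder_diameter = x$crowder_diameter,
    phi_c = x$phi_c,
    interactions = tab,
    bonds = bond_params(k = x$bonds$k, r0 = x$bonds$r0),
    dynamics = dynamics_params(dt = x$dynamics$dt, gamma = x$dynamics$gamma,
                               temperature = x$dynamics$temperature,
                               mass = unlist(x$dynamics$mass)),
    geometry = cylinder_geometry(x$geometry$diameter, x$geometry$length,
                                 mode = x$geometry$mode,
                                 wall_model = x$geometry$wall_model,
                                 bead_spacing = x$geometry$bead_spacing),
    seed = x$seed)
}

write_summary_json <- function(summary, path, extra = list()) {
  x <- c(unclass(summary), extra)
  x$se <- as.list(x$se)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
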