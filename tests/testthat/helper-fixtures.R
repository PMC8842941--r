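# Shared fixture builders (everything generated in code at test time).

# A slide whose patches are clearly separable: strong DAB neurites on clean
# tissue, no background confusers; used for the detector smoke benchmark.
separableSlidePatches <- function(seed, nNegatives = 25L) {
  sl <- generateSlide(slideSpec(height = 904L, width = 904L,
                                nDefinite = 15L, nProbable = 10L,
                                nPossible = 0L, nBackground = 0L,
                                spatialClustering = 0,
                                dabRange = c(0.6, 1.0), seed = seed))
  extractPatches(sl@image, sl@annotations, nNegatives = nNegatives,
                 seed = seed)
}

# Three well-separated planted Gaussian blobs (30 points each).
plantedBlobs <- function(seed = 42L, spread = 2, sep = 100) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(60, 0, spread), 30, 2),
               sweep(matrix(rnorm(60, 0, spread), 30, 2), 2, c(sep, 0), "+"),
               sweep(matrix(rnorm(60, 0, spread), 30, 2), 2, c(0, sep), "+"))
  list(points = pts, truth = rep(1:3, each = 30L))
}

# Random clustering instance for oracle-equivalence sweeps.
randomClusteringInstance <- function(seed, n = 50L, kmax = 5L) {
  set.seed(seed)
  K <- sample(2:kmax, 1L)
  labels <- sample(rep_len(seq_len(K), n))
  points <- matrix(runif(2L * n, 0, 100), n, 2L)
  cl <- new("APClustering", labels = as.integer(labels),
            exemplars = vapply(seq_len(K), function(k)
              which(labels == k)[1L], integer(1)),
            K = as.integer(K), converged = TRUE, iterations = 0L)
  cl@exemplars <- vapply(seq_len(K), function(k) which(labels == k)[1L],
                         integer(1))
  list(points = points, labels = labels, clustering = cl)
}

# Minimal annotation set with explicit geometry.
simpleAnnotations <- function(height = 400L, width = 400L) {
  sq <- function(r, c, half = 5) {
    rbind(c(r - half, c - half), c(r - half, c + half),
          c(r + half, c + half), c(r + half, c - half))
  }
  AnnotationSet(geometry = list(sq(100, 100), sq(300, 300), sq(200, 120)),
                class = c("foreground", "foreground", "background"),
                rank = c(3L, 1L, NA_integer_),
                height = height, width = width)
}
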