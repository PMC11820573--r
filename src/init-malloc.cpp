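// Large transient buffers (patch matrices, field grids) churn badly when
// glibc serves them with mmap/munmap on every allocation; raising the
// mmap threshold lets the heap reuse them.
#include <Rcpp.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
#ifdef __linux__
#include <dlfcn.h>
#include <sched.h>
#endif

// [[Rcpp::export]]
void tune_allocator_cpp() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
}

// OpenBLAS sizes its thread pool from the host's core count; inside a
// CPU-restricted container that oversubscribes the allowance and the
// spin-waiting threads slow small matrix products by orders of
// magnitude.  Clamp the pool to the cores this process may actually use.
// [[Rcpp::export]]
int tune_blas_threads_cpp() {
#ifdef __linux__
  cpu_set_t set;
  int avail = 0;
  if (sched_getaffinity(0, sizeof(set), &set) == 0) avail = CPU_COUNT(&set);
  if (avail < 1) avail = 1;
  typedef void (*setter_t)(int);
  setter_t setter = (setter_t)dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
  if (setter) {
    setter(avail);
    return avail;
  }
#endif
  return 0;
}
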