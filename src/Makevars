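# native-arch build: the package is compiled and run in the same container
CXXFLAGS += -O3 -march=native -funroll-loops
PKG_LIBS = $(BLAS_LIBS) $(LAPACK_LIBS) $(FLIBS)
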