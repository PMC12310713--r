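PKG_LIBS = -lz $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
CXXFLAGS += -O3 -funroll-loops
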